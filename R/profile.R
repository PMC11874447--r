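#' Spatial expression profile
#'
#' Container for a spots-by-genes expression matrix together with the 2-D
#' array coordinates of the spots.  This is the input object of the whole
#' pipeline: raw counts go through [filter_profile()] and
#' [normalize_profile()] before being handed to [tismod()].
#'
#' @param values numeric matrix, spots in rows, genes in columns.  Raw counts
#'   must be non-negative; no missing values are allowed.
#' @param coords numeric matrix or data frame with one row per spot and two
#'   columns (x, y) in platform array units.
#' @param gene_names character vector of unique gene names; defaults to the
#'   column names of `values`.
#' @param spot_ids character vector of unique spot identifiers; defaults to
#'   the row names of `values`.
#' @param platform `"low_res"` for spot-based arrays (ST / Visium style,
#'   one spot covers several cells) or `"high_res"` for bead- or
#'   cell-level platforms.  The two resolutions use different gene/spot
#'   filters, see [filter_profile()].
#' @param is_normalized logical flag; `FALSE` for raw counts.
#'
#' @return An object of class `"stm_profile"`: a list with elements
#'   `values`, `coords`, `gene_names`, `spot_ids`, `platform`,
#'   `is_normalized`.
#' @seealso [read_expression()], [filter_profile()], [normalize_profile()],
#'   [select_hvgs()], [tismod()]
#' @export
expression_profile <- function(values, coords, gene_names = colnames(values),
                               spot_ids = rownames(values),
                               platform = c("low_res", "high_res"),
                               is_normalized = FALSE) {
  platform <- match.arg(platform)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  coords <- as.matrix(coords)
  if (ncol(coords) != 2L)
    stop("'coords' must have two columns (x, y)", call. = FALSE)
  storage.mode(coords) <- "double"
  S <- nrow(values); L <- ncol(values)
  if (S < 2L) stop("profile must have at least 2 spots", call. = FALSE)
  if (L < 1L) stop("profile must have at least 1 gene", call. = FALSE)
  if (nrow(coords) != S)
    stop("'coords' must have one row per spot", call. = FALSE)
  if (is.null(gene_names)) gene_names <- paste0("gene", seq_len(L))
  if (is.null(spot_ids)) spot_ids <- paste0("spot", seq_len(S))
  gene_names <- as.character(gene_names)
  spot_ids <- as.character(spot_ids)
  if (length(gene_names) != L) stop("'gene_names' length mismatch", call. = FALSE)
  if (length(spot_ids) != S) stop("'spot_ids' length mismatch", call. = FALSE)
  if (anyDuplicated(gene_names))
    stop("duplicate gene names: ",
         paste(utils::head(unique(gene_names[duplicated(gene_names)]), 3L),
               collapse = ", "), call. = FALSE)
  if (anyDuplicated(spot_ids))
    stop("duplicate spot ids", call. = FALSE)
  if (anyNA(values) || any(!is.finite(values)))
    stop("'values' contains missing or non-finite entries", call. = FALSE)
  if (!is_normalized && any(values < 0))
    stop("raw counts must be non-negative", call. = FALSE)
  if (any(!is.finite(coords)))
    stop("'coords' contains non-finite entries", call. = FALSE)
  dimnames(values) <- list(spot_ids, gene_names)
  dimnames(coords) <- list(spot_ids, c("x", "y"))
  structure(list(values = values, coords = coords,
                 gene_names = gene_names, spot_ids = spot_ids,
                 platform = platform, is_normalized = is_normalized),
            class = "stm_profile")
}

#' @export
print.stm_profile <- function(x, ...) {
  cat(sprintf("Spatial expression profile: %d spots x %d genes (%s, %s)\n",
              nrow(x$values), ncol(x$values), x$platform,
              if (x$is_normalized) "normalized" else "raw counts"))
  invisible(x)
}

#' @export
dim.stm_profile <- function(x) dim(x$values)

# Parse ST-style spot identifiers "<x>x<y>" into coordinates.
# Accepts integer or fractional tokens ("10x13", "10.5x13.2").
parse_spot_coords <- function(spot_ids) {
  m <- regmatches(spot_ids,
                  regexec("^([-+]?[0-9]*\\.?[0-9]+)x([-+]?[0-9]*\\.?[0-9]+)$",
                          spot_ids))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("cannot parse coordinates from spot id(s): ",
         paste(utils::head(spot_ids[bad], 3L), collapse = ", "),
         " (expected '<x>x<y>' or a coordinate table)", call. = FALSE)
  xy <- t(vapply(m, function(g) as.numeric(g[2:3]), numeric(2)))
  colnames(xy) <- c("x", "y")
  xy
}

read_coord_table <- function(coord_file, spot_ids) {
  ct <- utils::read.table(coord_file, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(ct) < 3L)
    stop("coordinate table needs columns: spot id, x, y", call. = FALSE)
  idx <- match(spot_ids, as.character(ct[[1L]]))
  if (anyNA(idx))
    stop("coordinate table is missing spot(s): ",
         paste(utils::head(spot_ids[is.na(idx)], 3L), collapse = ", "),
         call. = FALSE)
  as.matrix(ct[idx, 2:3])
}

#' Read a spatial expression matrix
#'
#' Reads the three on-disk forms the pipeline accepts and returns a validated
#' [expression_profile()].  Spot order is preserved from the file.
#'
#' * `dense_table`: TSV/CSV with spots as rows and genes as columns, first
#'   column the spot id.  Coordinates are taken from a sidecar coordinate
#'   table (`coord_file`; columns spot id, x, y) when given, otherwise parsed
#'   from ST-convention spot names of the form `"<x>x<y>"`.
#' * `triplet_sparse`: a matrix-market triplet file (spots x genes) plus a
#'   gene-name text file (`gene_file`, one name per line) and a coordinate
#'   table (`coord_file`).
#' * `simulated_archive`: a directory written by [write_profile()] (also the
#'   layout of the simulation archives), containing `expression.tsv`,
#'   `coords.tsv` and `meta.json`.
#'
#' @param path file (or directory for `simulated_archive`) to read.
#' @param format one of `"dense_table"`, `"triplet_sparse"`,
#'   `"simulated_archive"`.
#' @param coord_file optional coordinate table (spot_id, x, y; TSV with
#'   header).
#' @param gene_file gene-name file, required for `triplet_sparse`.
#' @param sep field separator for `dense_table`; guessed from the file
#'   extension when `NULL` (`","` for `.csv`, tab otherwise).
#' @param platform,is_normalized passed to [expression_profile()];
#'   ignored for `simulated_archive`, whose metadata records them.
#' @return An `stm_profile`.
#' @export
read_expression <- function(path,
                            format = c("dense_table", "triplet_sparse",
                                       "simulated_archive"),
                            coord_file = NULL, gene_file = NULL, sep = NULL,
                            platform = "low_res", is_normalized = FALSE) {
  format <- match.arg(format)
  if (!file.exists(path))
    stop("input path does not exist: ", path, call. = FALSE)
  if (format == "dense_table") {
    if (is.null(sep))
      sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             stringsAsFactors = FALSE, check.names = FALSE,
                             row.names = 1L)
    if (nrow(tab) == 0L || ncol(tab) == 0L)
      stop("empty expression matrix in ", path, call. = FALSE)
    values <- as.matrix(tab)
    spot_ids <- rownames(tab)
    coords <- if (is.null(coord_file)) parse_spot_coords(spot_ids)
              else read_coord_table(coord_file, spot_ids)
    expression_profile(values, coords, gene_names = colnames(tab),
                       spot_ids = spot_ids, platform = platform,
                       is_normalized = is_normalized)
  } else if (format == "triplet_sparse") {
    if (is.null(coord_file) || is.null(gene_file))
      stop("'triplet_sparse' needs both 'coord_file' and 'gene_file'",
           call. = FALSE)
    mm <- Matrix::readMM(path)
    values <- as.matrix(mm)
    if (length(values) == 0L)
      stop("empty expression matrix in ", path, call. = FALSE)
    gene_names <- readLines(gene_file)
    gene_names <- gene_names[nzchar(gene_names)]
    if (length(gene_names) != ncol(values))
      stop("gene-name file length does not match matrix columns", call. = FALSE)
    ct <- utils::read.table(coord_file, header = TRUE, sep = "\t",
                            stringsAsFactors = FALSE, check.names = FALSE)
    if (nrow(ct) != nrow(values))
      stop("coordinate table rows do not match matrix rows", call. = FALSE)
    expression_profile(values, as.matrix(ct[, 2:3]),
                       gene_names = gene_names,
                       spot_ids = as.character(ct[[1L]]),
                       platform = platform, is_normalized = is_normalized)
  } else {
    meta_file <- file.path(path, "meta.json")
    meta <- if (file.exists(meta_file))
      jsonlite::read_json(meta_file, simplifyVector = TRUE) else list()
    prof <- read_expression(file.path(path, "expression.tsv"),
                            format = "dense_table",
                            coord_file = file.path(path, "coords.tsv"),
                            platform = if (!is.null(meta$platform))
                              meta$platform else "low_res",
                            is_normalized = isTRUE(meta$is_normalized))
    prof
  }
}

#' Write a profile archive
#'
#' Writes an `stm_profile` as a directory with `expression.tsv` (spots x
#' genes), `coords.tsv` and a JSON metadata sidecar, the format read back by
#' `read_expression(format = "simulated_archive")`.
#'
#' @param profile an `stm_profile`.
#' @param dir output directory, created if missing.
#' @param meta optional named list merged into the metadata sidecar
#'   (e.g. filters applied, seed).
#' @return `dir`, invisibly.
#' @export
write_profile <- function(profile, dir, meta = list()) {
  stopifnot(inherits(profile, "stm_profile"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tab <- data.frame(spot = profile$spot_ids,
                    as.data.frame(profile$values, check.names = FALSE),
                    check.names = FALSE)
  utils::write.table(tab, file.path(dir, "expression.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  ct <- data.frame(spot = profile$spot_ids, x = profile$coords[, 1L],
                   y = profile$coords[, 2L])
  utils::write.table(ct, file.path(dir, "coords.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  meta <- utils::modifyList(
    list(platform = profile$platform, is_normalized = profile$is_normalized,
         n_spots = nrow(profile$values), n_genes = ncol(profile$values),
         package_version = as.character(utils::packageVersion("tismod"))),
    meta)
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(dir)
}

# Subset helper keeping the object valid.
subset_profile <- function(profile, spots = NULL, genes = NULL) {
  v <- profile$values
  co <- profile$coords
  si <- profile$spot_ids
  gn <- profile$gene_names
  if (!is.null(genes)) { v <- v[, genes, drop = FALSE]; gn <- gn[genes] }
  if (!is.null(spots)) {
    v <- v[spots, , drop = FALSE]; co <- co[spots, , drop = FALSE]
    si <- si[spots]
  }
  expression_profile(v, co, gene_names = gn, spot_ids = si,
                     platform = profile$platform,
                     is_normalized = profile$is_normalized)
}
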