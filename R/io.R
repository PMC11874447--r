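#' Write a fitted model archive
#'
#' Serializes the posterior summaries of a fit as plain text: `loadings.tsv`
#' (modules x genes), `pip.tsv`, `maps.tsv` (spots x modules with
#' coordinates) and `report.json` (ELBO trace, selected decay rates and
#' length scales, active flags, gene centres, seed and settings echo).  The
#' archive can be read back with [read_tismod()] and used for transfer runs.
#'
#' @param object a fitted [tismod()] model.
#' @param dir output directory, created if missing.
#' @return `dir`, invisibly.
#' @export
write_tismod <- function(object, dir) {
  stopifnot(inherits(object, "tismod"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(x, file, label) {
    tab <- data.frame(label = rownames(x), as.data.frame(x,
                                                         check.names = FALSE),
                      check.names = FALSE)
    names(tab)[1L] <- label
    utils::write.table(tab, file.path(dir, file), sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  wt(object$loadings, "loadings.tsv", "module")
  wt(object$pip, "pip.tsv", "module")
  maps <- data.frame(spot = object$spot_ids, x = object$coords[, 1L],
                     y = object$coords[, 2L],
                     as.data.frame(object$maps, check.names = FALSE),
                     check.names = FALSE)
  utils::write.table(maps, file.path(dir, "maps.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  report <- list(
    C = object$C, seed = object$seed, init = object$init,
    converged = object$converged, n_iter = object$n_iter,
    elbo_trace = object$elbo, r_hat = object$r_hat,
    length_scales = object$length_scales, active = object$active,
    coordinate_scale = object$scale, r_grid = object$r_grid,
    centers = as.list(stats::setNames(object$centers, object$gene_names)),
    platform = object$platform,
    prior = unclass(object$prior), kernel = unclass(object$kernel),
    control = unclass(object$control),
    package_version = as.character(utils::packageVersion("tismod")))
  jsonlite::write_json(report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a fitted model archive
#'
#' Reconstructs a [tismod()] fit from a directory written by
#' [write_tismod()].  The restored object carries the posterior summaries
#' (loadings, PIPs, maps) and settings and supports all postprocessing and
#' [transfer()], but not `residuals()` (the expression matrix is not
#' archived).
#'
#' @param dir archive directory.
#' @return A `tismod` object.
#' @export
read_tismod <- function(dir) {
  rd <- function(file) {
    tab <- utils::read.table(file.path(dir, file), header = TRUE, sep = "\t",
                             check.names = FALSE, row.names = 1L)
    as.matrix(tab)
  }
  loadings <- rd("loadings.tsv")
  pip <- rd("pip.tsv")
  maps_tab <- utils::read.table(file.path(dir, "maps.tsv"), header = TRUE,
                                sep = "\t", check.names = FALSE)
  rep <- jsonlite::read_json(file.path(dir, "report.json"),
                             simplifyVector = TRUE)
  maps <- as.matrix(maps_tab[, -(1:3), drop = FALSE])
  rownames(maps) <- maps_tab$spot
  centers <- unlist(rep$centers)
  structure(list(
    loadings = loadings, pip = pip, maps = maps, map_var = NULL,
    r_hat = rep$r_hat, length_scales = rep$length_scales,
    active = rep$active, elbo = rep$elbo_trace, converged = rep$converged,
    n_iter = rep$n_iter, centers = centers[colnames(loadings)],
    gene_names = colnames(loadings), spot_ids = maps_tab$spot,
    coords = as.matrix(maps_tab[, 2:3]), platform = rep$platform,
    C = rep$C, prior = do.call(tismod_prior, as.list(rep$prior)),
    kernel = do.call(kernel_control, as.list(rep$kernel)),
    control = do.call(tismod_control, as.list(rep$control)),
    init = rep$init, seed = rep$seed, scale = rep$coordinate_scale,
    r_grid = rep$r_grid, y = NULL, state = NULL, call = NULL),
    class = "tismod")
}
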