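#' Write a scan result as TSV + JSON settings
#'
#' One TSV row per unique subset (anchor, weight, member pair ids, Q2,
#' CV-ANOVA p, position) plus a JSON file with the settings needed to
#' reproduce the scan.
#'
#' @param scan a `scan_result`.
#' @param tsv_path output table path.
#' @param settings_path optional JSON settings path.
#' @export
write_scan_tsv <- function(scan, tsv_path, settings_path = NULL) {
  stopifnot(inherits(scan, "scan_result"))
  df <- scan$subsets
  df$members <- vapply(scan$members, function(m) {
    paste(scan$coords$pair_id[m], collapse = ";")
  }, character(1))
  write_tsv(df, tsv_path)
  if (!is.null(settings_path)) {
    jsonlite::write_json(unclass(scan$settings), settings_path,
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Write a density or probability map as a TSV raster
#'
#' Long format: one row per cell with its two coordinates and value(s).
#'
#' @param map a `density_map` or `probability_map`.
#' @param path output path.
#' @export
write_map_tsv <- function(map, path) {
  df <- data.frame(ttd = rep(map$ttd, times = length(map$tbs)),
                   tbs = rep(map$tbs, each = length(map$ttd)))
  if (inherits(map, "density_map")) {
    df$count <- as.vector(map$counts)
  } else if (inherits(map, "probability_map")) {
    df$p <- as.vector(map$p)
    df$level <- as.character(as.vector(map$level))
  } else {
    stop("map must be a density_map or probability_map")
  }
  write_tsv(df, path)
  invisible(path)
}

#' Serialize an OPLS model (and optional CV result) to JSON
#'
#' Loadings, scores, coefficient, scaling record and, when supplied, the
#' cross-validation summary with its settings.
#'
#' @param model an `opls_model`.
#' @param path output path.
#' @param cv optional `cv_result`.
#' @export
write_model_json <- function(model, path, cv = NULL) {
  stopifnot(inherits(model, "opls_model"))
  obj <- list(w = model$w, p = model$p, t = model$t, b = model$b,
              n_ortho = model$n_ortho,
              scaling = model$scaling,
              variable_ids = model$variable_ids)
  if (model$n_ortho > 0L) {
    obj$W_o <- model$W_o
    obj$P_o <- model$P_o
  }
  if (!is.null(cv)) {
    obj$cv <- list(Q2 = cv$Q2, p_cvanova = cv$p_cvanova,
                   press = cv$press, y_pred = cv$y_pred,
                   computable = cv$computable,
                   n_components = cv$n_components,
                   settings = cv$settings)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
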