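# First-crossing extraction and reactive/unreactive labelling.

#' Index of the first frame crossing an interface
#'
#' The first stored frame with \eqn{\lambda \ge \lambda^c}; no interpolation
#' between frames is performed, and a path that already starts beyond
#' \eqn{\lambda^c} crosses at its first frame.
#'
#' @param path a [ppa_path].
#' @param lam_c crossing interface position.
#' @return 1-based frame index, or `NA_integer_` when the path never reaches
#'   `lam_c`.
#' @export
first_crossing_index <- function(path, lam_c) {
  i <- which(path$frames$lambda >= lam_c)
  if (!length(i)) NA_integer_ else i[1L]
}

#' Reactive/unreactive label of a path
#'
#' A path is reactive with respect to \eqn{\lambda^r} when its maximum
#' order-parameter value reaches \eqn{\lambda^r} (ties count as reactive).
#' The caller is responsible for only labelling paths that cross
#' \eqn{\lambda^c}; by continuity any path reaching \eqn{\lambda^r} first
#' crossed every \eqn{\lambda^c \le \lambda^r}.
#'
#' @param path a [ppa_path].
#' @param lam_r reaction interface position.
#' @return `"reactive"` or `"unreactive"`.
#' @export
label_path <- function(path, lam_r) {
  if (lambda_max(path) >= lam_r) "reactive" else "unreactive"
}

#' Build the weighted first-crossing sample set at a query
#'
#' For every `[i+]` path whose maximum reaches \eqn{\lambda^c}, extracts the
#' collective-variable values at the first-crossing frame together with the
#' path weight and the reactive/unreactive label with respect to
#' \eqn{\lambda^r}. Each qualifying path contributes exactly one sample (its
#' first crossing), never later recrossings.
#'
#' @param paths list of weighted [ppa_path] objects.
#' @param query a [ppa_query].
#' @param cv_names character vector of CV column names to carry.
#' @return A data.frame of class `ppa_samples` with columns `path_id`, the
#'   requested CVs, `weight`, `label`; attributes `lam_c`, `lam_r`,
#'   `cv_names`.
#' @export
build_sample_set <- function(paths, query, cv_names) {
  stopifnot(inherits(query, "ppa_query"))
  ens <- vapply(paths, `[[`, "", "ensemble")
  paths <- paths[ens != "0-"]
  if (!length(paths)) ppa_error("empty path set", "ppa_value_error")
  avail <- cv_names_of(paths[[1L]])
  missing <- setdiff(cv_names, avail)
  if (length(missing))
    ppa_error(sprintf("unknown CV '%s'; available: %s", missing[1L],
                      paste(avail, collapse = ", ")), "ppa_value_error")
  rows <- list()
  for (p in paths) {
    i <- first_crossing_index(p, query$lam_c)
    if (is.na(i)) next
    row <- data.frame(path_id = p$path_id)
    for (cv in cv_names) row[[cv]] <- p$frames[[cv]][i]
    row$weight <- p$weight
    row$label <- label_path(p, query$lam_r)
    rows[[length(rows) + 1L]] <- row
  }
  if (!length(rows))
    ppa_error("no path crosses lam_c", "ppa_value_error")
  s <- do.call(rbind, rows)
  rownames(s) <- NULL
  structure(s, lam_c = query$lam_c, lam_r = query$lam_r, cv_names = cv_names,
            class = c("ppa_samples", "data.frame"))
}

samples_cv_column <- function(s, cv = NULL) {
  cvs <- setdiff(names(s), c("path_id", "weight", "label"))
  if (is.null(cv)) {
    if (length(cvs) != 1L)
      ppa_error(sprintf(
        "sample set has %d CV columns (%s); name one explicitly",
        length(cvs), paste(cvs, collapse = ", ")), "ppa_value_error")
    cvs
  } else {
    if (!cv %in% cvs)
      ppa_error(sprintf("unknown CV '%s'; available: %s", cv,
                        paste(cvs, collapse = ", ")), "ppa_value_error")
    cv
  }
}

#' Average transition probability of a sample set
#'
#' The weighted fraction of reactive first-crossing samples,
#' \eqn{\bar p = W_r / W}. Identical (to rounding) to the ratio of
#' crossing-curve values \eqn{P_A(\lambda^r|\lambda_A) /
#' P_A(\lambda^c|\lambda_A)} on the same weighted paths.
#'
#' @param s a `ppa_samples` data.frame.
#' @return \eqn{\bar p \in [0, 1]}.
#' @export
mean_crossing_prob <- function(s) {
  W <- sum(s$weight)
  if (W <= 0) ppa_error("total weight is zero", "ppa_value_error")
  sum(s$weight[s$label == "reactive"]) / W
}
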