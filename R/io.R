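#' Read trial data from CSV
#'
#' The file has one row per classifier with columns `index`, `n1`, `x`, `c`
#' and optionally `lambda`, plus a single stage-2 row carrying the columns
#' `n2` and `y` (all other cells of that row empty).  Lines starting with
#' `#` are comments.
#'
#' @param path file path.
#' @param ranking optional [ranking_rule()]; defaults to the sensitivity
#'   ranking.
#' @return a fitted [twostage()] object.
#' @export
read_trial_csv <- function(path, ranking = NULL) {
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("n2", "y") %in% names(tab))) {
    stop("trial CSV must contain a stage-2 row with columns n2 and y")
  }
  s2 <- tab[!is.na(tab$n2), , drop = FALSE]
  cl <- tab[is.na(tab$n2), , drop = FALSE]
  if (nrow(s2) != 1) stop("exactly one stage-2 row (non-empty n2) expected")
  need <- c("index", "n1", "x", "c")
  miss <- setdiff(need, names(cl))
  if (length(miss)) stop("missing classifier columns: ",
                         paste(miss, collapse = ", "))
  cl <- cl[order(cl$index), , drop = FALSE]
  if (!identical(as.integer(cl$index), seq_len(nrow(cl)))) {
    stop("classifier indices must be 1..K")
  }
  design <- if (is.null(ranking)) {
    two_stage_design(n1 = cl$n1, c = cl$c, n2 = s2$n2)
  } else {
    two_stage_design(n1 = cl$n1, c = cl$c, n2 = s2$n2, ranking = ranking)
  }
  y <- if (is.na(s2$y)) NULL else as.integer(s2$y)
  twostage(x = cl$x, y = y, design = design)
}

#' Serialize estimates of a fitted trial as a JSON record
#'
#' @param object a fitted [twostage()] object.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
write_estimates_json <- function(object, path = NULL) {
  if (inherits(object, "twostage_stopped")) {
    rec <- list(stopped = TRUE)
  } else {
    sel <- object$selection
    rec <- list(
      stopped = FALSE,
      estimates = as.list(object$estimates),
      conditioning = list(
        M = sel$M, L = sel$L, z1 = object$x[sel$M] + object$y,
        support = list(lower = min(object$support$values),
                       upper = max(object$support$values),
                       kind = object$support$kind)))
  }
  js <- jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Write interval results as CSV
#'
#' One row per interval: method, level, bounds, width and, when applicable,
#' the alpha split, bootstrap replicate count and seed.
#'
#' @param results a list of `"interval_result"` objects.
#' @param path output path.
#' @return the data frame, invisibly.
#' @export
write_intervals_csv <- function(results, path) {
  rows <- lapply(results, function(r) {
    data.frame(
      method = r$method, level = r$level, lower = r$lower, upper = r$upper,
      width = r$upper - r$lower,
      alpha1 = if (is.null(r$alpha_split)) NA_real_ else r$alpha_split[1],
      alpha2 = if (is.null(r$alpha_split)) NA_real_ else r$alpha_split[2],
      B = if (is.null(r$replicates)) NA_integer_ else r$replicates,
      seed = if (is.null(r$seed)) NA_integer_ else r$seed)
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(out)
}
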