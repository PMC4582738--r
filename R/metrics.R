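# Recovery metrics for simulator truth sets.

#' Per-class Jaccard similarity between called and true domains
#'
#' For each class, the Jaccard index of the base-pair sets covered by
#' called and true domains of that class.
#'
#' @param called domain set with a `class` column.
#' @param truth truth intervals with a `class` column (e.g. a domain
#'   plan).
#' @param classes classes to score (default hyper and hypo).
#' @return named numeric vector of Jaccard indices.
#' @export
jaccard_by_class <- function(called, truth,
                             classes = c("hyper", "hypo")) {
  out <- setNames(rep(NA_real_, length(classes)), classes)
  for (cl in classes) {
    a <- reduce_intervals(called[called$class == cl, , drop = FALSE])
    b <- reduce_intervals(truth[truth$class == cl, , drop = FALSE])
    if (nrow(a) == 0 && nrow(b) == 0) next
    inter <- intersect_intervals(a, b)
    ibp <- sum(inter$end - inter$start)
    ubp <- sum(a$end - a$start) + sum(b$end - b$start) - ibp
    out[cl] <- if (ubp > 0) ibp / ubp else NA_real_
  }
  out
}
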