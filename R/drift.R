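#' Summarise (G)EBV changes between two evaluation runs
#'
#' Expresses per-animal changes in estimated breeding values between two
#' evaluation runs as a percentage of one additive genetic standard
#' deviation (SDa), summarised per animal class (e.g. genotyped x
#' has-new-phenotype). When standard errors of prediction are supplied the
#' change of each animal is also compared against `1.96 * SEP`, the 95%
#' bound on possible changes implied by its accuracy.
#'
#' @param run1,run2 named numeric vectors of (G)EBV over a common id set.
#' @param SDa additive genetic standard deviation (> 0), in the same units.
#' @param classes named character/factor vector assigning each animal to a
#'   class; default a single class `"all"`.
#' @param sep optional named vector of standard errors of prediction.
#' @return list of class `drift_summary` with `per_class` (data.frame:
#'   class, n, mean/sd/min/max change in % SDa), `per_animal` (data.frame
#'   with `change_pct` and, if `sep` given, `exceeds_95ci`) and `SDa`.
#' @export
evaluation_drift <- function(run1, run2, SDa, classes = NULL, sep = NULL) {
  if (SDa <= 0) stop("SDa must be positive")
  ids <- intersect(names(run1), names(run2))
  if (!length(ids)) stop("run1 and run2 share no animal ids")
  change <- (run2[ids] - run1[ids]) / SDa * 100
  if (is.null(classes)) classes <- stats::setNames(rep("all", length(ids)), ids)
  cls <- as.character(classes[ids])
  cls[is.na(cls)] <- "unclassified"
  per_animal <- data.frame(animal = ids, class = cls,
                           change_pct = as.numeric(change))
  if (!is.null(sep)) {
    s <- sep[ids]
    per_animal$sep <- as.numeric(s)
    per_animal$exceeds_95ci <- abs(run2[ids] - run1[ids]) > 1.96 * s
  }
  agg <- do.call(rbind, lapply(split(per_animal, per_animal$class),
    function(d) data.frame(class = d$class[1], n = nrow(d),
                           mean = mean(d$change_pct),
                           sd = stats::sd(d$change_pct),
                           min = min(d$change_pct),
                           max = max(d$change_pct))))
  rownames(agg) <- NULL
  structure(list(per_class = agg, per_animal = per_animal, SDa = SDa),
            class = "drift_summary")
}

#' @exportS3Method base::print
print.drift_summary <- function(x, ...) {
  cat("(G)EBV changes between runs, % of one SDa (SDa =", x$SDa, ")\n")
  print(x$per_class, row.names = FALSE)
  if (!is.null(x$per_animal$exceeds_95ci))
    cat(sprintf("%d of %d animals exceed 1.96 x SEP\n",
                sum(x$per_animal$exceeds_95ci), nrow(x$per_animal)))
  invisible(x)
}
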