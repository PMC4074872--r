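## Phenotype differentiation statistics: group summaries, between-ecotype
## and between-environment differences with the percentage conventions of
## ecotype comparison tables, two-sample tests and trait correlations.

.checkPhenotypeTable <- function(table) {
  req <- c("accession", "ecotype", "environment", "trait", "value")
  stopifnot(all(req %in% names(table)))
  invisible(table)
}

#' Per-ecotype mean and standard deviation of a trait
#'
#' @param table phenotype data.frame (`accession`, `ecotype`,
#'   `environment`, `trait`, `value`).
#' @param trait,environment which cell of the design to summarize.
#' @return data.frame with `ecotype`, `n`, `mean`, `sd` (sample sd),
#'   rounded to one decimal in `meanRounded`/`sdRounded`.
#' @export
groupSummary <- function(table, trait, environment) {
  .checkPhenotypeTable(table)
  sub <- table[table$trait == trait & table$environment == environment, ]
  if (!nrow(sub)) stop("no rows for ", trait, " / ", environment)
  sp <- split(sub$value, sub$ecotype)
  if (any(vapply(sp, length, integer(1)) < 2))
    stop("need at least 2 values per ecotype group")
  data.frame(ecotype = names(sp),
             n = vapply(sp, length, integer(1)),
             mean = vapply(sp, mean, numeric(1)),
             sd = vapply(sp, sd, numeric(1)),
             meanRounded = roundHalfUp(vapply(sp, mean, numeric(1)), 1),
             sdRounded = roundHalfUp(vapply(sp, sd, numeric(1)), 1),
             row.names = NULL)
}

#' Between-ecotype difference and percentage
#'
#' Absolute mean difference and its percentage of the irrigated-ecotype
#' mean (the convention that reproduces published comparison tables:
#' e.g. means 89.5 and 116.1 give 26.6 and 29.7%), both rounded to one
#' decimal with halves away from zero.
#'
#' @param meanIrrigated,meanUpland group means for one trait and
#'   environment.
#' @return named numeric: `diff`, `percent`. `percent` is `NA` (with a
#'   warning) when the irrigated mean is 0.
#' @export
ecotypeDifference <- function(meanIrrigated, meanUpland) {
  d <- abs(meanUpland - meanIrrigated)
  if (meanIrrigated == 0) {
    warning("irrigated mean is 0; percentage undefined")
    return(c(diff = roundHalfUp(d, 1), percent = NA_real_))
  }
  c(diff = roundHalfUp(d, 1),
    percent = roundHalfUp(d / meanIrrigated * 100, 1))
}

#' Between-environment change as a signed percentage
#'
#' Signed change from the irrigated-condition mean (`meanEnv1`) to the
#' dry-land-condition mean (`meanEnv2`) of one ecotype and trait:
#' `(meanEnv2 - meanEnv1) / meanEnv1 * 100`, one decimal. A root length
#' moving from 27.2 to 29.9 cm is +9.9%.
#'
#' @param meanEnv1 mean under the irrigated condition (the base).
#' @param meanEnv2 mean under the dry-land condition.
#' @return named numeric: `diff` (signed, one decimal), `percent`
#'   (signed, one decimal; `NA` with a warning when `meanEnv1 == 0`).
#' @export
environmentChange <- function(meanEnv1, meanEnv2) {
  d <- meanEnv2 - meanEnv1
  if (meanEnv1 == 0) {
    warning("base mean is 0; percentage undefined")
    return(c(diff = roundHalfUp(d, 1), percent = NA_real_))
  }
  c(diff = roundHalfUp(d, 1),
    percent = roundHalfUp(d / meanEnv1 * 100, 1))
}

#' Two-sample Student's t test
#'
#' Equal-variance, unpaired, two-sided Student's t (Welch available via
#' `varEqual = FALSE`). When the pooled variance is zero and the means are
#' equal, `t = 0` and `P = 1` by convention.
#'
#' @param x,y numeric vectors (>= 2 values each).
#' @param varEqual assume equal variances (default TRUE).
#' @return named numeric: `t`, `p`.
#' @export
twoSampleT <- function(x, y, varEqual = TRUE) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) return(c(t = 0, p = 1))
    return(c(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  tt <- t.test(x, y, var.equal = varEqual)
  c(t = unname(tt$statistic), p = tt$p.value)
}

#' Pearson correlation between two traits
#'
#' Pairs the two traits by accession within one environment (non-missing
#' pairs only) and returns the Pearson correlation with its two-sided P
#' value from the t transform.
#'
#' @param table phenotype data.frame.
#' @param traitA,traitB trait names.
#' @param environment environment to correlate within.
#' @return named numeric: `rho`, `p`, `n`. Errors when fewer than 3
#'   complete pairs or a trait has zero variance.
#' @export
traitCorrelation <- function(table, traitA, traitB, environment) {
  .checkPhenotypeTable(table)
  sub <- table[table$environment == environment &
                 table$trait %in% c(traitA, traitB), ]
  wide <- merge(
    sub[sub$trait == traitA, c("accession", "value")],
    sub[sub$trait == traitB, c("accession", "value")],
    by = "accession", suffixes = c(".a", ".b"))
  wide <- wide[complete.cases(wide), ]
  if (nrow(wide) < 3) stop("need at least 3 complete pairs")
  if (var(wide$value.a) == 0 || var(wide$value.b) == 0)
    stop("zero variance in one of the traits")
  ct <- cor.test(wide$value.a, wide$value.b, method = "pearson")
  c(rho = unname(ct$estimate), p = ct$p.value, n = nrow(wide))
}

#' Full ecotype-differentiation summary table
#'
#' Applies [groupSummary()] and [ecotypeDifference()] to every
#' (trait, environment) cell present in the table, mirroring the layout
#' of a published phenotype-differentiation table.
#'
#' @param table phenotype data.frame.
#' @param varEqual passed to [twoSampleT()].
#' @return data.frame with one row per trait x environment: group means,
#'   sds, t-test P, absolute difference and percentage.
#' @export
phenotypeDifferentiation <- function(table, varEqual = TRUE) {
  .checkPhenotypeTable(table)
  cells <- unique(table[c("trait", "environment")])
  out <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    tr <- cells$trait[i]; env <- cells$environment[i]
    gs <- groupSummary(table, tr, env)
    mi <- gs$mean[gs$ecotype == "irrigated"]
    mu <- gs$mean[gs$ecotype == "upland"]
    sub <- table[table$trait == tr & table$environment == env, ]
    tt <- twoSampleT(sub$value[sub$ecotype == "upland"],
                     sub$value[sub$ecotype == "irrigated"],
                     varEqual = varEqual)
    ed <- ecotypeDifference(mi, mu)
    data.frame(trait = tr, environment = env,
               irrigatedMean = mi, uplandMean = mu,
               irrigatedSd = gs$sd[gs$ecotype == "irrigated"],
               uplandSd = gs$sd[gs$ecotype == "upland"],
               p = tt["p"], diff = ed["diff"], percent = ed["percent"],
               row.names = NULL)
  }))
  out
}
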