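# Per-region group comparison of cFos densities: volume normalization,
# Shapiro-Wilk normality screening, Welch unpaired t-tests, and a single
# whole-brain Benjamini-Hochberg FDR correction.

#' Convert cell counts to volume-normalized densities
#'
#' Each entry becomes `count / volume_mm3` for the matching region
#' (cells per mm^3).
#'
#' @param cohort a `cfos_cohort`.
#' @param ontology region catalogue supplying the volumes; defaults to the
#'   cohort's own.
#' @return Object of class `density_matrix`: list with `values` (animals x
#'   regions numeric matrix), `genotype`, `animal_id`, `ontology`.
#' @export
compute_density <- function(cohort, ontology = cohort$ontology) {
  stopifnot(inherits(cohort, "cfos_cohort"),
            inherits(ontology, "region_ontology"))
  miss <- setdiff(colnames(cohort$counts), ontology$acronym)
  if (length(miss))
    stop("ontology lacks volume for region(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  vol <- ontology$volume_mm3[match(colnames(cohort$counts),
                                   ontology$acronym)]
  values <- sweep(cohort$counts, 2, vol, `/`)
  structure(list(values = values, genotype = cohort$genotype,
                 animal_id = cohort$animal_id, ontology = ontology),
            class = "density_matrix")
}

#' Build a density matrix from a cohort's continuous latent densities
#'
#' Synthetic cohorts carry the continuous densities from which integer
#' counts were rounded. Correlation analyses can be run on either
#' representation; the continuous one is free of the rank ties that count
#' quantization introduces in low-volume regions, which matters for
#' exact-null p-values. Only available for generated cohorts.
#'
#' @param cohort a `cfos_cohort` produced by [generate_cohort()].
#' @return A `density_matrix` backed by the pre-rounding densities.
#' @export
latent_density_matrix <- function(cohort) {
  stopifnot(inherits(cohort, "cfos_cohort"))
  if (is.null(cohort$latent_density))
    stop("cohort has no latent densities (loaded from file?)")
  structure(list(values = cohort$latent_density,
                 genotype = cohort$genotype,
                 animal_id = cohort$animal_id,
                 ontology = cohort$ontology),
            class = "density_matrix")
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning just the W
#' statistic and p-value, with the small-sample preconditions made
#' explicit (3 <= n <= 5000, non-constant data).
#'
#' @param values numeric vector.
#' @return List with `W` and `p`.
#' @export
shapiro_wilk <- function(values) {
  n <- length(values)
  if (n < 3 || n > 5000) stop("Shapiro-Wilk requires 3 <= n <= 5000")
  if (stats::var(values) == 0)
    stop("Shapiro-Wilk is undefined for zero-variance data")
  st <- stats::shapiro.test(values)
  list(W = unname(st$statistic), p = st$p.value)
}

#' Welch's unequal-variance two-sample t-test
#'
#' Returns the t statistic (`mean(group_a) - mean(group_b)` in the
#' numerator), Welch-Satterthwaite fractional degrees of freedom, and the
#' two-sided p-value. With groups of sizes n1 and n2 the df always lies in
#' `(min(n1, n2) - 1, n1 + n2 - 2]`.
#'
#' @param group_a,group_b numeric vectors, each of length >= 2.
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(group_a, group_b) {
  if (length(group_a) < 2 || length(group_b) < 2)
    stop("each group needs at least 2 observations")
  if (stats::var(group_a) == 0 && stats::var(group_b) == 0)
    stop("both groups have zero variance; t is undefined")
  ht <- stats::t.test(group_a, group_b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}

#' Benjamini-Hochberg FDR correction
#'
#' Step-up adjusted q-values (via [stats::p.adjust()]) and the reject set
#' at level `alpha`.
#'
#' @param p_values numeric vector of p-values in `[0, 1]`.
#' @param alpha FDR level, default 0.05.
#' @return List with `q` (same order as input) and `reject` (logical).
#' @export
bh_fdr <- function(p_values, alpha = 0.05) {
  if (anyNA(p_values) || any(p_values < 0 | p_values > 1))
    stop("p-values must lie in [0, 1]")
  q <- stats::p.adjust(p_values, method = "BH")
  list(q = q, reject = q <= alpha)
}

#' Per-region two-group comparison with whole-brain FDR
#'
#' For each region: Shapiro-Wilk normality per group (reported, not used
#' to switch tests), Welch t between the two genotypes, and a single BH
#' correction across all testable regions jointly. Regions constant in
#' both groups are flagged untestable and excluded from the FDR family.
#'
#' @param densities a `density_matrix` with exactly two genotype levels.
#' @param alpha FDR level for the reject flag, default 0.05.
#' @return data.frame of class `group_comparison` with columns `region`,
#'   `t`, `df`, `p_raw`, `q_fdr`, `reject`, `shapiro_p_<group1>`,
#'   `shapiro_p_<group2>`, `untestable`.
#' @export
compare_groups <- function(densities, alpha = 0.05) {
  stopifnot(inherits(densities, "density_matrix"))
  gl <- levels(droplevels(densities$genotype))
  if (length(gl) != 2)
    stop("compare_groups needs exactly 2 genotypes, found ", length(gl))
  X <- densities$values
  ia <- densities$genotype == gl[1]
  ib <- densities$genotype == gl[2]
  R <- ncol(X)
  t_stat <- df <- p_raw <- sw_a <- sw_b <- rep(NA_real_, R)
  untestable <- logical(R)
  for (j in seq_len(R)) {
    a <- X[ia, j]; b <- X[ib, j]
    if (stats::var(a) == 0 && stats::var(b) == 0) {
      untestable[j] <- TRUE
      next
    }
    w <- welch_t(a, b)
    t_stat[j] <- w$t; df[j] <- w$df; p_raw[j] <- w$p
    sw_a[j] <- tryCatch(shapiro_wilk(a)$p, error = function(e) NA_real_)
    sw_b[j] <- tryCatch(shapiro_wilk(b)$p, error = function(e) NA_real_)
  }
  if (any(untestable))
    message(sum(untestable),
            " region(s) constant in both groups: excluded from FDR family")
  q_fdr <- rep(NA_real_, R)
  reject <- rep(NA, R)
  testable <- !untestable
  if (any(testable)) {
    adj <- bh_fdr(p_raw[testable], alpha)
    q_fdr[testable] <- adj$q
    reject[testable] <- adj$reject
  }
  out <- data.frame(region = colnames(X), t = t_stat, df = df,
                    p_raw = p_raw, q_fdr = q_fdr, reject = reject,
                    sw_a, sw_b, untestable = untestable,
                    stringsAsFactors = FALSE)
  names(out)[names(out) == "sw_a"] <- paste0("shapiro_p_", gl[1])
  names(out)[names(out) == "sw_b"] <- paste0("shapiro_p_", gl[2])
  attr(out, "groups") <- gl
  class(out) <- c("group_comparison", "data.frame")
  out
}

#' Write per-region comparison results as TSV
#' @param comparison a `group_comparison`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_group_comparison <- function(comparison, path) {
  stopifnot(inherits(comparison, "group_comparison"))
  write.table(as.data.frame(comparison), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
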