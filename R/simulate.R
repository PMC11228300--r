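# Synthetic cohort generator: genotype-labelled animal x region cell
# counts with planted rank-correlation structure.
#
# Latent per-animal region vectors are drawn from a Gaussian copula whose
# correlation is block-structured; marginals are log-normal densities
# (baseline x effect multiplier); counts are round(density x volume). A
# planted block target rho* is the SPEARMAN correlation, so the latent
# Pearson correlation is r = 2 * sin(pi * rho* / 6), the inverse of
# rho_S = (6/pi) * asin(r/2) for a bivariate Gaussian.

#' Specify a synthetic cFos cohort
#'
#' @param ontology a [region_ontology].
#' @param n_per_group named integer vector, genotype -> animal count
#'   (default `c(WT = 6, KO = 5)`); every count must be >= 3.
#' @param baseline_log_mean per-region location of log-density (cells/mm^3
#'   scale); scalar recycled, default `log(300)`.
#' @param dispersion per-region scale of log-density; scalar recycled,
#'   default 0.4.
#' @param effect_map optional data.frame with columns
#'   `genotype,region,effect`: multiplicative density shifts.
#' @param correlation_blocks list of blocks, each a list with elements
#'   `genotype`, `regions` (acronyms) and `rho` (target pairwise Spearman
#'   correlation, in (-1, 1)). When two blocks of one genotype cover the
#'   same pair, the larger target wins.
#' @param seed integer seed; identical specs generate identical cohorts.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(ontology, n_per_group = c(WT = 6, KO = 5),
                        baseline_log_mean = log(300), dispersion = 0.4,
                        effect_map = NULL, correlation_blocks = list(),
                        seed = 1L) {
  stopifnot(inherits(ontology, "region_ontology"))
  if (is.null(names(n_per_group)) || any(!nzchar(names(n_per_group))))
    stop("n_per_group must be a named vector (genotype -> count)")
  if (any(n_per_group < 3))
    stop("every group needs at least 3 animals")
  nr <- nrow(ontology)
  baseline_log_mean <- rep_len(baseline_log_mean, nr)
  dispersion <- rep_len(dispersion, nr)
  if (any(dispersion < 0)) stop("dispersion must be non-negative")
  if (!is.null(effect_map)) {
    stopifnot(is.data.frame(effect_map),
              all(c("genotype", "region", "effect") %in% names(effect_map)))
    bad <- setdiff(effect_map$region, ontology$acronym)
    if (length(bad))
      stop("effect_map names unknown region(s): ", paste(bad, collapse = ", "))
    if (any(effect_map$effect <= 0)) stop("effects must be positive")
    bad_g <- setdiff(effect_map$genotype, names(n_per_group))
    if (length(bad_g))
      stop("effect_map names unknown genotype(s): ",
           paste(bad_g, collapse = ", "))
  }
  for (b in correlation_blocks) {
    if (!all(c("genotype", "regions", "rho") %in% names(b)))
      stop("each correlation block needs genotype, regions and rho")
    if (!b$genotype %in% names(n_per_group))
      stop("block genotype '", b$genotype, "' not in n_per_group")
    bad <- setdiff(b$regions, ontology$acronym)
    if (length(bad))
      stop("correlation block names unknown region(s): ",
           paste(bad, collapse = ", "))
    if (length(b$regions) < 2) stop("a correlation block needs >= 2 regions")
    if (abs(b$rho) >= 1) stop("target block rho must lie in (-1, 1)")
  }
  structure(list(ontology = ontology,
                 n_per_group = n_per_group,
                 baseline_log_mean = baseline_log_mean,
                 dispersion = dispersion,
                 effect_map = effect_map,
                 correlation_blocks = correlation_blocks,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# latent Gaussian correlation matrix for one genotype
.latent_sigma <- function(spec, genotype) {
  acr <- spec$ontology$acronym
  R <- length(acr)
  blocks <- Filter(function(b) b$genotype == genotype,
                   spec$correlation_blocks)
  if (!length(blocks)) return(NULL)  # identity; caller takes fast path
  Sigma <- diag(R)
  dimnames(Sigma) <- list(acr, acr)
  for (b in blocks) {
    r <- 2 * sin(pi * b$rho / 6)
    idx <- match(b$regions, acr)
    for (i in idx) for (j in idx) {
      if (i != j) {
        Sigma[i, j] <- if (b$rho >= 0) max(Sigma[i, j], r) else
          ifelse(Sigma[i, j] == 0, r, Sigma[i, j])
      }
    }
  }
  Sigma
}

#' Generate a synthetic cohort of cell counts
#'
#' Draws one animal x region count table per genotype under the Gaussian
#' copula described in [cohort_spec()]. Deterministic given the spec
#' (including its seed).
#'
#' @param spec a `cohort_spec`.
#' @return Object of class `cfos_cohort`: list with `counts` (integer
#'   matrix, animals x regions), `genotype` (factor), `animal_id`,
#'   `latent_density` (the pre-rounding densities, cells/mm^3), `ontology`
#'   and `spec`.
#' @examples
#' ont <- load_region_table(default_region_table())
#' coh <- generate_cohort(cohort_spec(ont, seed = 7))
#' dim(coh$counts)
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  ont <- spec$ontology
  acr <- ont$acronym
  R <- length(acr)
  counts <- NULL; dens_all <- NULL
  genotype <- character(0); animal_id <- character(0)
  for (g in names(spec$n_per_group)) {
    n <- spec$n_per_group[[g]]
    Sigma <- .latent_sigma(spec, g)
    Z <- matrix(stats::rnorm(n * R), n, R)
    if (!is.null(Sigma)) {
      U <- tryCatch(chol(Sigma), error = function(e)
        stop("implied latent correlation matrix for genotype '", g,
             "' is not positive definite; use smaller target rho or ",
             "smaller blocks", call. = FALSE))
      Z <- Z %*% U
    }
    eff <- rep(1, R)
    if (!is.null(spec$effect_map)) {
      em <- spec$effect_map[spec$effect_map$genotype == g, , drop = FALSE]
      if (nrow(em)) eff[match(em$region, acr)] <- em$effect
    }
    dens <- exp(sweep(sweep(Z, 2, spec$dispersion, `*`),
                      2, spec$baseline_log_mean, `+`))
    dens <- sweep(dens, 2, eff, `*`)
    cnt <- round(sweep(dens, 2, ont$volume_mm3, `*`))
    storage.mode(cnt) <- "integer"
    cnt[cnt < 0L] <- 0L
    counts <- rbind(counts, cnt)
    dens_all <- rbind(dens_all, dens)
    genotype <- c(genotype, rep(g, n))
    animal_id <- c(animal_id, paste0(g, "_", seq_len(n)))
  }
  colnames(counts) <- acr
  colnames(dens_all) <- acr
  rownames(counts) <- animal_id
  rownames(dens_all) <- animal_id
  structure(list(counts = counts,
                 genotype = factor(genotype, levels = names(spec$n_per_group)),
                 animal_id = animal_id,
                 latent_density = dens_all,
                 ontology = ont,
                 spec = spec),
            class = "cfos_cohort")
}

#' Preset cohort emulating the WT vs knockout contrast
#'
#' A ready-made [cohort_spec] for the study conditions: WT n = 6, KO n = 5
#' over the 196-region catalogue, a mean-shift increase in VTA density in
#' the knockout, a dense planted default-mode block (plus a
#' hippocampal-accumbens social block) in the knockout, and planted
#' salience and amygdala-VTA social blocks in the wild type. This mirrors
#' the qualitative pattern of denser default-mode co-activation and
#' sparser salience co-activation in the knockout.
#'
#' @param ontology region catalogue; defaults to the shipped 196-region
#'   synthetic fixture.
#' @param networks network definitions used to pick block members; default
#'   the shipped file.
#' @param n_wt,n_ko group sizes (defaults 6 and 5).
#' @param seed integer seed.
#' @return A `cohort_spec`.
#' @export
preset_cohort_spec <- function(ontology = load_region_table(default_region_table()),
                               networks = load_network_definitions(
                                 default_network_definitions(), ontology),
                               n_wt = 6, n_ko = 5, seed = 1L) {
  blocks <- list(
    list(genotype = "WT", regions = networks$salience, rho = 0.9),
    list(genotype = "WT", regions = c("VTA", "ACB", "MD", "MPO"),
         rho = 0.85),
    list(genotype = "KO", regions = networks$default_mode, rho = 0.9),
    list(genotype = "KO", regions = c("VTA", "ACB", "MD", "MPO", "CEA"),
         rho = 0.85))
  cohort_spec(ontology,
              n_per_group = c(WT = n_wt, KO = n_ko),
              effect_map = data.frame(genotype = "KO", region = "VTA",
                                      effect = 1.6),
              correlation_blocks = blocks,
              seed = seed)
}

#' Write / read a cohort count table as TSV
#'
#' Rows are animals; the first two columns are `animal_id` and `genotype`,
#' followed by one integer column per region in ontology order.
#'
#' @param cohort a `cfos_cohort`.
#' @param path output path.
#' @return `path` invisibly (write) or a `cfos_cohort` (read).
#' @export
write_counts_table <- function(cohort, path) {
  stopifnot(inherits(cohort, "cfos_cohort"))
  df <- data.frame(animal_id = cohort$animal_id,
                   genotype = as.character(cohort$genotype),
                   cohort$counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_table
#' @param ontology the `region_ontology` matching the table's region columns.
#' @export
read_counts_table <- function(path, ontology) {
  stopifnot(inherits(ontology, "region_ontology"))
  df <- .read_delim_auto(path)
  if (!all(c("animal_id", "genotype") %in% names(df)))
    stop("counts table needs `animal_id` and `genotype` columns")
  regions <- setdiff(names(df), c("animal_id", "genotype"))
  miss <- setdiff(ontology$acronym, regions)
  if (length(miss))
    stop("counts table is missing region column(s): ",
         paste(utils::head(miss, 5), collapse = ", "))
  counts <- as.matrix(df[, ontology$acronym, drop = FALSE])
  storage.mode(counts) <- "integer"
  if (any(counts < 0)) stop("counts must be non-negative")
  rownames(counts) <- df$animal_id
  structure(list(counts = counts,
                 genotype = factor(df$genotype,
                                   levels = unique(df$genotype)),
                 animal_id = df$animal_id,
                 latent_density = NULL,
                 ontology = ontology,
                 spec = NULL),
            class = "cfos_cohort")
}

#' @export
print.cfos_cohort <- function(x, ...) {
  cat("cFos cohort:", nrow(x$counts), "animals x", ncol(x$counts),
      "regions\n")
  print(table(genotype = x$genotype))
  invisible(x)
}
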