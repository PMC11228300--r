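# Per-genotype inter-regional co-activation networks: Spearman rho
# matrices across animals, thresholded adjacency, network density,
# signed-edge counts, threshold sweeps and functional-subnetwork edges.

#' Per-genotype Spearman correlation matrix over regions
#'
#' Computes Spearman's rho (and a companion p-value matrix) for every
#' region pair across the animals of one genotype. Constant region
#' columns give undefined correlations: their rows/columns are `NA` and
#' they are flagged in `defined`. For tie-free pairs with `n <= 9`
#' animals the p-values are exact permutation p-values; otherwise the t
#' approximation is used (see [spearman_rho()]).
#'
#' @param densities a `density_matrix`.
#' @param genotype which genotype label to use (>= 3 animals).
#' @return Object of class `cofos_corr`: list with `genotype`, `rho` and
#'   `p` (square matrices), `n` (animals used), `regions`, `defined`
#'   (logical per region), `ties` (logical per region).
#' @examples
#' ont <- load_region_table(default_region_table())
#' coh <- generate_cohort(cohort_spec(ont, seed = 1))
#' cm <- correlation_matrix(compute_density(coh), "WT")
#' cm$rho[1:3, 1:3]
#' @export
correlation_matrix <- function(densities, genotype) {
  stopifnot(inherits(densities, "density_matrix"))
  idx <- densities$genotype == genotype
  n <- sum(idx)
  if (n < 3) stop("genotype '", genotype, "' has ", n,
                  " animals; need >= 3")
  X <- densities$values[idx, , drop = FALSE]
  regions <- colnames(X)
  R <- ncol(X)
  defined <- apply(X, 2, function(v) stats::var(v) > 0)
  ties <- apply(X, 2, function(v) anyDuplicated(v) > 0)
  rho <- suppressWarnings(stats::cor(X, method = "spearman"))
  rho[!defined, ] <- NA_real_
  rho[, !defined] <- NA_real_
  diag(rho) <- ifelse(defined, 1, NA_real_)
  p <- matrix(NA_real_, R, R, dimnames = dimnames(rho))
  ut <- which(upper.tri(rho), arr.ind = TRUE)
  ok <- defined[ut[, 1]] & defined[ut[, 2]]
  pair_exact <- ok & n <= 9 & !ties[ut[, 1]] & !ties[ut[, 2]]
  r_ut <- rho[ut]
  p_ut <- rep(NA_real_, nrow(ut))
  if (any(pair_exact))
    p_ut[pair_exact] <- .spearman_p_exact(r_ut[pair_exact], n)
  tie_free_large <- ok & !pair_exact & !ties[ut[, 1]] & !ties[ut[, 2]]
  if (any(tie_free_large))
    p_ut[tie_free_large] <- .spearman_p_approx(r_ut[tie_free_large], n,
                                               tie_free = TRUE)
  tied <- ok & !pair_exact & !tie_free_large
  if (any(tied))
    p_ut[tied] <- .spearman_p_approx(r_ut[tied], n, tie_free = FALSE)
  p[ut] <- p_ut
  p[lower.tri(p)] <- t(p)[lower.tri(p)]
  structure(list(genotype = genotype, rho = rho, p = p, n = n,
                 regions = regions, defined = defined, ties = ties),
            class = "cofos_corr")
}

#' Threshold a correlation matrix into a binary adjacency matrix
#'
#' Two selection modes, matching the two rules used for co-activation
#' edge calling: `abs_rho` keeps pairs with `|rho| >= tau` (inclusive:
#' pairs at exactly the threshold survive), `fdr_p` keeps pairs whose
#' BH-adjusted p-value over the family of all defined pairs is `<= alpha`.
#' Undefined pairs are never edges.
#'
#' @param corr a `cofos_corr`.
#' @param tau threshold on `|rho|`, in (0, 1); default 0.8.
#' @param mode `"abs_rho"` (default) or `"fdr_p"`.
#' @param alpha FDR level for `fdr_p` mode, default 0.05.
#' @return Object of class `cofos_adj`: list with `genotype`, `adj`
#'   (binary symmetric matrix, zero diagonal), `tau`, `mode`, `alpha`,
#'   `regions`, `defined`.
#' @export
threshold_adjacency <- function(corr, tau = 0.8,
                                mode = c("abs_rho", "fdr_p"),
                                alpha = 0.05) {
  stopifnot(inherits(corr, "cofos_corr"))
  mode <- match.arg(mode)
  if (!is.numeric(tau) || length(tau) != 1 || tau <= 0 || tau >= 1)
    stop("tau must lie strictly inside (0, 1)")
  R <- length(corr$regions)
  A <- matrix(0L, R, R, dimnames = dimnames(corr$rho))
  ut <- upper.tri(A)
  if (mode == "abs_rho") {
    hit <- !is.na(corr$rho) & abs(corr$rho) >= tau - 1e-12
    A[ut & hit] <- 1L
  } else {
    pv <- corr$p[ut]
    sel <- !is.na(pv)
    if (any(sel)) {
      q <- rep(NA_real_, length(pv))
      q[sel] <- bh_fdr(pv[sel], alpha)$q
      hitv <- !is.na(q) & q <= alpha
      ind <- which(ut)
      A[ind[hitv]] <- 1L
    }
  }
  A[lower.tri(A)] <- t(A)[lower.tri(A)]
  structure(list(genotype = corr$genotype, adj = A, tau = tau,
                 mode = mode, alpha = alpha, regions = corr$regions,
                 defined = corr$defined),
            class = "cofos_adj")
}

#' Network density of a binary adjacency matrix
#'
#' The proportion of realized connections relative to the total potential
#' connections: `edges / (R * (R - 1) / 2)` over the R regions with
#' defined correlations.
#'
#' @param adj a `cofos_adj`, or a plain binary symmetric matrix with zero
#'   diagonal.
#' @return A single number in `[0, 1]`.
#' @export
network_density <- function(adj) {
  if (inherits(adj, "cofos_adj")) {
    A <- adj$adj[adj$defined, adj$defined, drop = FALSE]
  } else {
    A <- adj
    stopifnot(is.matrix(A), nrow(A) == ncol(A))
    if (any(A != t(A)) || any(diag(A) != 0))
      stop("adjacency must be symmetric with zero diagonal")
  }
  R <- nrow(A)
  if (R < 2) stop("network density needs at least 2 regions")
  sum(A[upper.tri(A)]) / (R * (R - 1) / 2)
}

#' Density and signed-edge counts across a threshold sweep
#'
#' Applies increasingly stringent `|rho|` thresholds and records, per
#' threshold, the network density and the counts of surviving positive
#' and negative correlations. Edge sets are nested, so density is
#' non-increasing along the sweep.
#'
#' @param corr a `cofos_corr`.
#' @param thresholds ascending thresholds, default `c(0.7, 0.8, 0.9)`.
#' @return data.frame with columns `genotype`, `threshold`, `density`,
#'   `n_edges`, `n_positive`, `n_negative`.
#' @export
density_sweep <- function(corr, thresholds = c(0.7, 0.8, 0.9)) {
  stopifnot(inherits(corr, "cofos_corr"))
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly ascending")
  rows <- lapply(thresholds, function(tau) {
    adj <- threshold_adjacency(corr, tau = tau, mode = "abs_rho")
    ut <- upper.tri(adj$adj)
    edge <- adj$adj[ut] == 1L
    rs <- corr$rho[ut]
    data.frame(genotype = corr$genotype, threshold = tau,
               density = network_density(adj),
               n_edges = sum(edge),
               n_positive = sum(edge & rs > 0),
               n_negative = sum(edge & rs < 0))
  })
  do.call(rbind, rows)
}

#' Edges within a functional subnetwork
#'
#' Region pairs with both endpoints in the network and `|rho| >= tau`
#' (inclusive), the data behind per-network circle plots. Undefined pairs
#' are excluded.
#'
#' @param corr a `cofos_corr`.
#' @param members character vector of member acronyms (or one element of a
#'   `network_definitions` list).
#' @param network_name label recorded in the output.
#' @param tau threshold on `|rho|`, default 0.8.
#' @return data.frame (class `edge_list`) with columns `region_1`,
#'   `region_2`, `rho`, `network`, ordered by decreasing `|rho|`.
#' @export
subnetwork_edges <- function(corr, members, network_name = "network",
                             tau = 0.8) {
  stopifnot(inherits(corr, "cofos_corr"))
  members <- as.character(members)
  unknown <- setdiff(members, corr$regions)
  if (length(unknown))
    stop("network '", network_name, "' member(s) not in the matrix: ",
         paste(unknown, collapse = ", "))
  resolvable <- members[corr$defined[match(members, corr$regions)]]
  if (length(resolvable) < 2)
    stop("network '", network_name,
         "' has fewer than 2 resolvable members")
  pairs <- utils::combn(resolvable, 2)
  rho <- corr$rho[cbind(pairs[1, ], pairs[2, ])]
  keep <- !is.na(rho) & abs(rho) >= tau - 1e-12
  out <- data.frame(region_1 = pairs[1, keep], region_2 = pairs[2, keep],
                    rho = rho[keep],
                    network = rep(network_name, sum(keep)),
                    stringsAsFactors = FALSE)
  out <- out[order(-abs(out$rho), out$region_1, out$region_2), ,
             drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("edge_list", "data.frame")
  out
}

#' Write an edge list as TSV with 8-decimal rho formatting
#'
#' @param edges an `edge_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(edges, path) {
  df <- as.data.frame(edges)
  df$rho <- formatC(df$rho, digits = 8, format = "fg", flag = "#")
  df$rho <- sub("\\.?0*$", "", df$rho)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Restrict two correlation matrices to their common defined regions
#'
#' Keeps only regions whose correlations are defined (non-constant
#' columns) in BOTH genotypes, so that density comparisons are made over
#' an identical region set. This is the region-count adjustment used
#' before comparing whole-brain densities across genotypes.
#'
#' @param corr_a,corr_b `cofos_corr` objects sharing an ontology.
#' @return List of the two restricted `cofos_corr` objects.
#' @export
restrict_to_common_regions <- function(corr_a, corr_b) {
  stopifnot(inherits(corr_a, "cofos_corr"), inherits(corr_b, "cofos_corr"))
  common <- intersect(corr_a$regions[corr_a$defined],
                      corr_b$regions[corr_b$defined])
  if (length(common) == 0)
    stop("no regions are defined in both genotypes")
  restrict <- function(cm) {
    keep <- match(common, cm$regions)
    cm$rho <- cm$rho[keep, keep, drop = FALSE]
    cm$p <- cm$p[keep, keep, drop = FALSE]
    cm$regions <- common
    cm$defined <- cm$defined[keep]
    cm$ties <- cm$ties[keep]
    cm
  }
  list(restrict(corr_a), restrict(corr_b))
}

#' Fit per-genotype co-activation networks
#'
#' The one-stop fit: for every genotype in the density matrix, estimates
#' the Spearman correlation matrix across animals, thresholds it into an
#' adjacency matrix at `tau` under the chosen selection mode, runs the
#' threshold sweep, and (optionally) extracts functional-subnetwork edge
#' lists. Both genotypes always use the same mode and threshold; mixing
#' selection rules across genotypes would make density comparisons
#' meaningless and is not supported.
#'
#' @param densities a `density_matrix`.
#' @param tau edge threshold on `|rho|`, default 0.8.
#' @param thresholds sweep thresholds, default `c(0.7, 0.8, 0.9)`.
#' @param mode edge selection mode, `"abs_rho"` (default) or `"fdr_p"`.
#' @param alpha FDR level for `fdr_p`, default 0.05.
#' @param networks optional `network_definitions` (named list of member
#'   acronyms) for subnetwork edge lists.
#' @return Object of class `cofos_network`: list with `correlations`,
#'   `adjacency`, `density` (named per genotype), `sweep` (data.frame),
#'   `subnetworks` (nested list genotype -> network -> `edge_list`),
#'   `settings`, `call`.
#' @examples
#' ont <- load_region_table(default_region_table())
#' coh <- generate_cohort(preset_cohort_spec(ont, seed = 1))
#' fit <- cofos_network(compute_density(coh))
#' fit
#' @export
cofos_network <- function(densities, tau = 0.8,
                          thresholds = c(0.7, 0.8, 0.9),
                          mode = c("abs_rho", "fdr_p"), alpha = 0.05,
                          networks = NULL) {
  stopifnot(inherits(densities, "density_matrix"))
  mode <- match.arg(mode)
  genotypes <- levels(droplevels(densities$genotype))
  correlations <- lapply(genotypes, function(g)
    correlation_matrix(densities, g))
  names(correlations) <- genotypes
  adjacency <- lapply(correlations, threshold_adjacency, tau = tau,
                      mode = mode, alpha = alpha)
  dens <- vapply(adjacency, network_density, numeric(1))
  sweep_tab <- do.call(rbind, lapply(correlations, density_sweep,
                                     thresholds = thresholds))
  rownames(sweep_tab) <- NULL
  subnetworks <- NULL
  if (!is.null(networks)) {
    subnetworks <- lapply(correlations, function(cm)
      lapply(stats::setNames(names(networks), names(networks)),
             function(nm) subnetwork_edges(cm, networks[[nm]], nm, tau)))
  }
  structure(list(correlations = correlations, adjacency = adjacency,
                 density = dens, sweep = sweep_tab,
                 subnetworks = subnetworks,
                 settings = list(tau = tau, thresholds = thresholds,
                                 mode = mode, alpha = alpha),
                 call = match.call()),
            class = "cofos_network")
}

#' @export
print.cofos_network <- function(x, ...) {
  cat("Co-activation network fit (", x$settings$mode, ", tau = ",
      x$settings$tau, ")\n", sep = "")
  for (g in names(x$density)) {
    cm <- x$correlations[[g]]
    cat(sprintf("  %s: n = %d animals, %d regions, density = %.4f\n",
                g, cm$n, sum(cm$defined), x$density[[g]]))
  }
  invisible(x)
}

#' @export
summary.cofos_network <- function(object, ...) {
  edge_counts <- NULL
  if (!is.null(object$subnetworks)) {
    edge_counts <- do.call(rbind, lapply(names(object$subnetworks),
      function(g) data.frame(genotype = g,
                             network = names(object$subnetworks[[g]]),
                             n_edges = vapply(object$subnetworks[[g]],
                                              nrow, integer(1)),
                             row.names = NULL)))
  }
  structure(list(density = object$density, sweep = object$sweep,
                 subnetwork_edges = edge_counts,
                 settings = object$settings),
            class = "summary.cofos_network")
}

#' @export
print.summary.cofos_network <- function(x, ...) {
  cat("Whole-brain network density (|rho| >=", x$settings$tau, "):\n")
  print(round(x$density, 4))
  cat("\nThreshold sweep:\n")
  print(x$sweep, row.names = FALSE)
  if (!is.null(x$subnetwork_edges)) {
    cat("\nFunctional-subnetwork edge counts:\n")
    print(x$subnetwork_edges, row.names = FALSE)
  }
  invisible(x)
}

#' @export
plot.cofos_network <- function(x, ...) {
  gs <- names(x$correlations)
  old <- graphics::par(mfrow = c(1, length(gs)), mar = c(1, 1, 3, 1))
  on.exit(graphics::par(old))
  pal <- grDevices::colorRampPalette(c("#2166AC", "white", "#B2182B"))(64)
  for (g in gs) {
    r <- x$correlations[[g]]$rho
    r[is.na(r)] <- 0
    graphics::image(t(r[rev(seq_len(nrow(r))), ]), col = pal,
                    zlim = c(-1, 1), axes = FALSE,
                    main = paste0(g, " Spearman rho"), ...)
  }
  invisible(x)
}

#' @export
print.cofos_corr <- function(x, ...) {
  ut <- x$rho[upper.tri(x$rho)]
  cat("Spearman correlation matrix (", x$genotype, "): ",
      length(x$regions), " regions, n = ", x$n, " animals\n", sep = "")
  cat(sprintf("  defined pairs: %d; |rho| >= 0.8: %d\n",
              sum(!is.na(ut)), sum(abs(ut) >= 0.8 - 1e-12, na.rm = TRUE)))
  invisible(x)
}

#' Write a square matrix (correlation or adjacency) as TSV
#' @param m a `cofos_corr`, `cofos_adj`, or plain matrix.
#' @param path output path.
#' @param what for `cofos_corr`: `"rho"` or `"p"`.
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(m, path, what = "rho") {
  M <- if (inherits(m, "cofos_corr")) m[[what]] else
    if (inherits(m, "cofos_adj")) m$adj else m
  df <- data.frame(region = rownames(M), M, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
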