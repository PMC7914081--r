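#' Per-species population time series from lattice snapshots
#'
#' Counts the occupied sites of each species in every snapshot (lagged
#' individuals count: they occupy positions) — the lattice analogue of
#' integrating each species over the 2-D domain at each time.
#'
#' @param snapshots A list of `ca_lattice` objects sharing dimensions, or a
#'   `ca_run` (whose per-step counts are returned directly).
#' @param n_species Number of species in the universe.
#' @return A list of class `population_series`: `steps` (integer vector),
#'   `counts` (species x steps matrix), `species_ids`.
#' @export
population_series <- function(snapshots, n_species = NULL) {
  if (inherits(snapshots, "ca_run")) {
    return(structure(list(steps = as.integer(colnames(snapshots$counts)),
                          counts = snapshots$counts,
                          species_ids = rownames(snapshots$counts)),
                     class = "population_series"))
  }
  stopifnot(is.list(snapshots), length(snapshots) >= 1)
  dims <- vapply(snapshots, function(l) dim(l$species), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("snapshots must share lattice dimensions")
  if (is.null(n_species))
    n_species <- max(1L, max(vapply(snapshots, function(l) max(l$species), integer(1))))
  counts <- vapply(snapshots, function(l) cpp_species_counts(l$species, n_species),
                   integer(n_species))
  counts <- matrix(counts, nrow = n_species)
  steps <- vapply(snapshots, function(l) l$step_index, integer(1))
  structure(list(steps = as.integer(steps), counts = counts,
                 species_ids = seq_len(n_species)),
            class = "population_series")
}

#' Simpson alpha diversity
#'
#' Gini--Simpson index \eqn{1 - \sum_i p_i^2} with \eqn{p_i} the relative
#' abundances; high values mean high richness and evenness.  The inverse
#' form \eqn{1 / \sum_i p_i^2} is available via `variant`.
#'
#' @param counts Non-negative abundance vector with positive sum.
#' @param variant `"gini"` (default, in \[0, 1\]) or `"inverse"`.
#' @return Diversity value.
#' @examples
#' simpson_alpha(c(25, 25, 25, 25)) # 0.75
#' @export
simpson_alpha <- function(counts, variant = c("gini", "inverse")) {
  variant <- match.arg(variant)
  if (any(counts < 0)) stop("counts must be non-negative")
  tot <- sum(counts)
  if (tot <= 0) stop("counts must have a positive sum")
  p2 <- sum((counts / tot)^2)
  if (variant == "gini") 1 - p2 else 1 / p2
}

#' Simpson diversity dynamics of a run
#'
#' @param series A `population_series` (or `ca_run`).
#' @inheritParams simpson_alpha
#' @return Data frame with columns `step`, `simpson_alpha` (NA where the
#'   community is empty).
#' @export
simpson_series <- function(series, variant = "gini") {
  if (inherits(series, "ca_run")) series <- population_series(series)
  vals <- apply(series$counts, 2, function(cc) {
    if (sum(cc) <= 0) NA_real_ else simpson_alpha(cc, variant)
  })
  data.frame(step = series$steps, simpson_alpha = as.numeric(vals))
}

.standardize_vectors <- function(vectors, bounds = species_param_bounds()) {
  nm <- colnames(vectors)
  lo <- vapply(nm, function(k) bounds[[k]][1], numeric(1))
  hi <- vapply(nm, function(k) bounds[[k]][2], numeric(1))
  sweep(sweep(vectors, 2, lo, "-"), 2, hi - lo, "/")
}

#' Hierarchical clustering of the climax community with model selection
#'
#' Clusters surviving-species parameter vectors under every candidate
#' (distance, linkage) pair, computes the cophenetic correlation of each
#' tree with the original distances, and selects the pair with the maximal
#' coefficient.  Vectors are min--max standardized to \[0, 1\] per
#' coordinate using the published interval bounds, so probabilities and
#' step counts are commensurable.  Centroid and median linkage are run on
#' squared distances with heights mapped back, as those methods require.
#'
#' @param vectors Numeric matrix, one row per surviving species, columns
#'   named by parameter (the 11-vector).
#' @param distances Candidate distance names (any of `"minkowski"`,
#'   `"euclidean"`, `"manhattan"`, `"maximum"`).
#' @param linkages Candidate linkage names (any of `"centroid"`,
#'   `"median"`, `"average"`, `"complete"`, `"single"`, `"ward.D2"`).
#' @param minkowski_p Minkowski exponent (default 2).
#' @param standardize Min--max standardize first.
#' @param bounds Interval bounds for standardization.
#' @return A list of class `cluster_selection`: `results` (data frame with
#'   `distance`, `linkage`, `cophenetic_r`, `selected`), `trees` (named list
#'   of `hclust` objects), `selected` (name of the best pair).
#' @export
cluster_climax <- function(vectors,
                           distances = c("minkowski", "manhattan", "maximum"),
                           linkages = c("centroid", "median", "average",
                                        "complete", "single", "ward.D2"),
                           minkowski_p = 2, standardize = TRUE,
                           bounds = species_param_bounds()) {
  vectors <- as.matrix(vectors)
  if (nrow(vectors) < 3)
    stop("insufficient data: need at least 3 surviving species to cluster")
  if (standardize) vectors <- .standardize_vectors(vectors, bounds)
  if (all(stats::dist(vectors) == 0))
    stop("degenerate input: all species vectors are identical")

  res <- list()
  trees <- list()
  for (dn in distances) {
    d <- stats::dist(vectors, method = dn, p = minkowski_p)
    for (ln in linkages) {
      if (ln %in% c("centroid", "median")) {
        hc <- stats::hclust(d^2, method = ln)
        hc$height <- sqrt(pmax(hc$height, 0))
      } else {
        hc <- stats::hclust(d, method = ln)
      }
      coph <- stats::cophenetic(hc)
      r <- suppressWarnings(stats::cor(as.vector(d), as.vector(coph)))
      key <- paste(dn, ln, sep = "+")
      trees[[key]] <- hc
      res[[key]] <- data.frame(distance = dn, linkage = ln,
                               cophenetic_r = r, stringsAsFactors = FALSE)
    }
  }
  results <- do.call(rbind, res)
  rownames(results) <- NULL
  results$selected <- seq_len(nrow(results)) == which.max(results$cophenetic_r)
  structure(list(results = results, trees = trees,
                 selected = paste(results$distance[results$selected],
                                  results$linkage[results$selected], sep = "+")),
            class = "cluster_selection")
}

#' @export
print.cluster_selection <- function(x, ...) {
  cat("Hierarchical clustering model selection (cophenetic correlation):\n")
  print(x$results[order(-x$results$cophenetic_r), ], row.names = FALSE)
  invisible(x)
}

#' Export a clustering tree in Newick format
#'
#' @param x A `cluster_selection`.
#' @param path Output file.
#' @param which Tree key (`"distance+linkage"`); default the selected pair.
#' @export
write_cluster_newick <- function(x, path, which = x$selected) {
  phy <- ape::as.phylo(x$trees[[which]])
  ape::write.tree(phy, file = path)
  invisible(path)
}

#' @rdname cluster_climax
#' @param x A `cluster_selection`.
#' @export
cluster_report <- function(x) x$results

#' Surviving species at climax
#'
#' @param run A `ca_run`.
#' @return Integer ids of species with positive abundance at the final step.
#' @export
surviving_species <- function(run) {
  which(run$counts[, ncol(run$counts)] > 0)
}

#' Is the run at a climax (quasi-stationary) state?
#'
#' The climax criterion: total occupancy varies by less than `tol`
#' (relative range) over the last `window` fraction of steps.
#'
#' @param run A `ca_run`.
#' @param tol Relative variation threshold (default 5%).
#' @param window Fraction of the run to examine (default last 10%).
#' @return Logical.
#' @export
is_climax <- function(run, tol = 0.05, window = 0.10) {
  tot <- colSums(run$counts)
  n <- length(tot)
  idx <- seq.int(max(1L, n - ceiling(window * n) + 1L), n)
  w <- tot[idx]
  if (mean(w) == 0) return(TRUE)
  (max(w) - min(w)) / mean(w) < tol
}

#' Spatial aggregation of similar species
#'
#' Statistic: mean Euclidean distance between the (standardized) parameter
#' vectors of all Moore-adjacent occupied pairs.  Null: permutations of the
#' species labels over the occupied sites.  The returned z-score
#' `(observed - null mean) / null sd` is negative when similar species
#' aggregate into patches.
#'
#' @param lat A `ca_lattice` with at least 2 occupied sites.
#' @param species A `species_table`.
#' @param n_perm Number of label permutations.
#' @param seed Optional RNG seed.
#' @param standardize Min--max standardize vectors first.
#' @return List with `z`, `observed`, `null_mean`, `null_sd`, `n_pairs`,
#'   `degenerate` (TRUE when the null has zero variance, e.g. one species).
#' @export
spatial_aggregation <- function(lat, species, n_perm = 199, seed = NULL,
                                standardize = TRUE) {
  .check_lattice(lat)
  if (!is.null(seed)) set.seed(seed)
  sp <- lat$species
  if (sum(sp > 0) < 2) stop("insufficient data: fewer than 2 occupied sites")
  X <- as.matrix(species[, .param_names])
  if (standardize) X <- .standardize_vectors(X)
  D <- as.matrix(stats::dist(X))

  R <- nrow(sp); C <- ncol(sp)
  shift <- function(m, di, dj) {
    ri <- ((seq_len(R) - 1 + di) %% R) + 1
    cj <- ((seq_len(C) - 1 + dj) %% C) + 1
    m[ri, cj, drop = FALSE]
  }
  # each unordered Moore-adjacent pair appears exactly once across E, S, SE, SW
  offsets <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  a_all <- integer(0); b_all <- integer(0)
  for (o in offsets) {
    nb <- shift(sp, o[1], o[2])
    sel <- sp > 0 & nb > 0
    a_all <- c(a_all, sp[sel])
    b_all <- c(b_all, nb[sel])
  }
  n_pairs <- length(a_all)
  if (n_pairs == 0)
    return(list(z = NA_real_, observed = NA_real_, null_mean = NA_real_,
                null_sd = NA_real_, n_pairs = 0L, degenerate = TRUE))
  observed <- mean(D[cbind(a_all, b_all)])

  occ_idx <- which(sp > 0)
  labels <- sp[occ_idx]
  # permuting labels over occupied sites == relabelling the pair endpoints,
  # so record each pair endpoint once as an occupied-site rank
  rank_mat <- matrix(NA_integer_, R, C)
  rank_mat[occ_idx] <- seq_along(occ_idx)
  a_rk <- integer(0); b_rk <- integer(0)
  for (o in offsets) {
    nb <- shift(rank_mat, o[1], o[2])
    sel <- !is.na(rank_mat) & !is.na(nb)
    a_rk <- c(a_rk, rank_mat[sel])
    b_rk <- c(b_rk, nb[sel])
  }
  null_stats <- vapply(seq_len(n_perm), function(k) {
    perm <- labels[sample.int(length(labels))]
    mean(D[cbind(perm[a_rk], perm[b_rk])])
  }, numeric(1))
  mu0 <- mean(null_stats)
  sd0 <- stats::sd(null_stats)
  degenerate <- !is.finite(sd0) || sd0 == 0
  z <- if (degenerate) NA_real_ else (observed - mu0) / sd0
  list(z = z, observed = observed, null_mean = mu0, null_sd = sd0,
       n_pairs = n_pairs, degenerate = degenerate)
}

#' Count post-transient local maxima of a population series
#'
#' Light running-median smoothing, then strict local maxima with a
#' prominence filter, counted over the second half of the series.  Used to
#' flag the asynchronous-oscillation signature of lag-driven coexistence.
#'
#' @param x Numeric series (one species' counts over steps).
#' @param min_prominence Minimum peak prominence as a fraction of the series
#'   range.
#' @param transient Fraction of the series discarded as transient.
#' @return Integer number of peaks.
#' @export
count_peaks <- function(x, min_prominence = 0.05, transient = 0.5) {
  n <- length(x)
  if (n < 10) return(0L)
  x <- x[seq.int(floor(transient * n) + 1L, n)]
  k <- min(9L, (length(x) %/% 2) * 2 - 1L)
  if (k >= 3) x <- stats::runmed(x, k)
  rng <- max(x) - min(x)
  if (rng == 0) return(0L)
  peaks <- 0L
  last_min <- x[1]
  i <- 2L
  while (i < length(x)) {
    if (x[i] > x[i - 1] && x[i] >= x[i + 1]) {
      # prominence vs the lowest point since the previous counted peak
      if ((x[i] - last_min) / rng >= min_prominence) {
        peaks <- peaks + 1L
        last_min <- x[i]
      }
    }
    last_min <- min(last_min, x[i])
    i <- i + 1L
  }
  peaks
}

#' Plot population curves of a run
#'
#' @param run A `ca_run`.
#' @param path Optional PNG path; when `NULL`, plots to the active device.
#' @export
plot_population_series <- function(run, path = NULL) {
  if (!is.null(path)) {
    grDevices::png(path, width = 900, height = 600)
    on.exit(grDevices::dev.off())
  }
  graphics::matplot(as.integer(colnames(run$counts)), t(run$counts),
                    type = "l", lty = 1, col = run$species$color,
                    xlab = "step", ylab = "population")
  invisible(run)
}
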