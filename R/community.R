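#' Published parameter intervals for the behavioural parameter vector
#'
#' Sampling boxes for the 11-component species vector
#' `[alpha1, alpha2, alpha3, beta1, beta2, beta3, m, p, d, Lat, n]`:
#' lag-entry probability tiers for collaborators (`alpha1 > alpha2 > alpha3`)
#' and scammers (`beta1 < beta2 < beta3`), move/proliferation probability
#' `m`, death probability after lag overrun `p`, natural death probability
#' `d` (`d < p`), lag-phase time `Lat` (steps, integer) and maximum-lag
#' factor `n` (integer).
#'
#' @return A named list of `c(lower, upper)` intervals.
#' @export
species_param_bounds <- function() {
  list(alpha1 = c(0.7, 1), alpha2 = c(0.3, 0.7), alpha3 = c(0, 0.3),
       beta1 = c(0, 0.3), beta2 = c(0.3, 0.7), beta3 = c(0.7, 1),
       m = c(0, 0.2), p = c(0.8, 1), d = c(0.1, 0.3),
       Lat = c(6, 10), n = c(1, 3))
}

.param_names <- c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3",
                  "m", "p", "d", "Lat", "n")

#' Community / simulation configuration
#'
#' @param N Initial species richness, `>= 2`.
#' @param N_p Collaborator fraction of species, in \[0, 1\].
#' @param M Target initial cells per species.  Treated as a target: when
#'   `N * M` exceeds `max_fill` times the lattice size, per-species counts
#'   are rescaled proportionally.
#' @param M_p Collaborator fraction of total initial cells, in \[0, 1\].
#' @param lattice_rows,lattice_cols Lattice dimensions, `>= 8`.
#' @param steps Simulation length in steps.
#' @param seed RNG seed (integer) or `NULL`.
#' @param max_fill Maximum initial occupancy fraction of the lattice, (0, 1].
#' @param lag_enabled Apply the lag-induction (delay response) rules.
#' @param mll_literal Use the literal same-type neighbourhood sum instead of
#'   the opposite-role count (sensitivity switch).
#' @param snapshot_stride Steps between stored lattice snapshots.
#' @return A list of class `community_config`.
#' @export
community_config <- function(N = 20, N_p = 0.5, M = 500, M_p = 0.5,
                             lattice_rows = 100, lattice_cols = 100,
                             steps = 1000, seed = NULL, max_fill = 0.5,
                             lag_enabled = TRUE, mll_literal = FALSE,
                             snapshot_stride = 10) {
  cfg <- list(N = as.integer(N), N_p = N_p, M = M, M_p = M_p,
              lattice_rows = as.integer(lattice_rows),
              lattice_cols = as.integer(lattice_cols),
              steps = as.integer(steps),
              seed = if (is.null(seed)) NULL else as.integer(seed),
              max_fill = max_fill, lag_enabled = isTRUE(lag_enabled),
              mll_literal = isTRUE(mll_literal),
              snapshot_stride = as.integer(snapshot_stride))
  validate_config(cfg)
  structure(cfg, class = "community_config")
}

validate_config <- function(cfg) {
  if (cfg$N < 2) stop("configuration error: N must be >= 2")
  if (cfg$lattice_rows < 8 || cfg$lattice_cols < 8)
    stop("configuration error: lattice dimensions must be >= 8")
  for (k in c("N_p", "M_p")) {
    if (cfg[[k]] < 0 || cfg[[k]] > 1)
      stop(sprintf("configuration error: %s must lie in [0, 1]", k))
  }
  if (cfg$max_fill <= 0 || cfg$max_fill > 1)
    stop("configuration error: max_fill must lie in (0, 1]")
  if (cfg$steps < 0) stop("configuration error: steps must be >= 0")
  if (cfg$M < 1) stop("configuration error: M must be >= 1")
  invisible(cfg)
}

# uniform draw respecting a strict ordering among three tier coordinates;
# resamples the offending coordinate (bounded attempts) so draws stay
# uniform on the constrained box
.draw_ordered <- function(bounds, names3, decreasing, max_try = 100) {
  v <- vapply(names3, function(nm) stats::runif(1, bounds[[nm]][1], bounds[[nm]][2]),
              numeric(1))
  ok <- function(v) all(if (decreasing) diff(v) < 0 else diff(v) > 0)
  tries <- 0
  while (!ok(v)) {
    tries <- tries + 1
    if (tries > max_try)
      stop("generation error: could not satisfy tier ordering within ",
           max_try, " resampling attempts")
    bad <- which(if (decreasing) diff(v) >= 0 else diff(v) <= 0)[1] + 1L
    v[bad] <- stats::runif(1, bounds[[names3[bad]]][1], bounds[[names3[bad]]][2])
  }
  v
}

#' Monte-Carlo generation of a species pool
#'
#' Draws `N` species parameter vectors uniformly and independently from the
#' published intervals ([species_param_bounds()]), with `round(N * N_p)`
#' collaborators and the rest scammers.  Tier orderings
#' `alpha1 > alpha2 > alpha3`, `beta1 < beta2 < beta3` and `d < p` are
#' enforced (guaranteed by the default disjoint intervals; a bounded
#' resampling guard covers custom intervals).  `Lat` and `n` are integers.
#'
#' @param cfg A [community_config()].
#' @param bounds Parameter intervals, as from [species_param_bounds()].
#' @param seed Optional seed; defaults to `cfg$seed`.
#' @return A data frame of class `species_table`: one row per species with
#'   `species_id`, `role`, the 11 parameters, and `color` (hex).
#' @export
sample_community <- function(cfg, bounds = species_param_bounds(), seed = cfg$seed) {
  validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  n_collab <- round(cfg$N * cfg$N_p)
  roles <- c(rep("collaborator", n_collab), rep("scammer", cfg$N - n_collab))
  rows <- lapply(seq_len(cfg$N), function(i) {
    a <- .draw_ordered(bounds, c("alpha1", "alpha2", "alpha3"), decreasing = TRUE)
    b <- .draw_ordered(bounds, c("beta1", "beta2", "beta3"), decreasing = FALSE)
    tries <- 0
    repeat {
      p <- stats::runif(1, bounds$p[1], bounds$p[2])
      d <- stats::runif(1, bounds$d[1], bounds$d[2])
      if (d < p) break
      tries <- tries + 1
      if (tries > 100) stop("generation error: could not satisfy d < p")
    }
    data.frame(species_id = i, role = roles[i],
               alpha1 = a[1], alpha2 = a[2], alpha3 = a[3],
               beta1 = b[1], beta2 = b[2], beta3 = b[3],
               m = stats::runif(1, bounds$m[1], bounds$m[2]), p = p, d = d,
               Lat = sample(seq(bounds$Lat[1], bounds$Lat[2]), 1),
               n = sample(seq(bounds$n[1], bounds$n[2]), 1))
  })
  sp <- do.call(rbind, rows)
  sp$color <- vapply(seq_len(nrow(sp)), function(i) assign_color(sp[i, ], bounds),
                     character(1))
  class(sp) <- c("species_table", "data.frame")
  sp
}

#' Map a species parameter vector to a display colour
#'
#' The vector magnitude (Euclidean norm of the 11 parameters, normalized by
#' the norm of the interval upper bounds so the scalar lies in \[0, 1\]) is
#' passed through a fixed perceptually uniform colormap (viridis).  Nearby
#' parameter vectors therefore get nearby colours; no randomness is
#' involved.
#'
#' @param sp One row of a species table (or any list with the 11 parameters).
#' @param bounds Parameter intervals used for normalization.
#' @return Hex colour string.
#' @export
assign_color <- function(sp, bounds = species_param_bounds()) {
  v <- vapply(.param_names, function(nm) as.numeric(sp[[nm]]), numeric(1))
  s <- color_scalar(v, bounds)
  ramp <- grDevices::colorRamp(grDevices::hcl.colors(256, "Viridis"))
  rgbv <- ramp(s)
  grDevices::rgb(rgbv[1], rgbv[2], rgbv[3], maxColorValue = 255)
}

#' @rdname assign_color
#' @param v Numeric 11-vector in the order
#'   `alpha1..alpha3, beta1..beta3, m, p, d, Lat, n`.
#' @export
color_scalar <- function(v, bounds = species_param_bounds()) {
  upper <- vapply(.param_names, function(nm) bounds[[nm]][2], numeric(1))
  s <- sqrt(sum(v^2)) / sqrt(sum(upper^2))
  min(max(s, 0), 1)
}

#' Create an empty lattice
#'
#' The lattice is a torus: indices wrap in both directions, so every site
#' has 8 Moore neighbours and 48 radius-3 outer candidates.
#'
#' @param rows,cols Dimensions.
#' @return An object of class `ca_lattice`: integer matrices `species`
#'   (0 = vacant), `is_lag`, `lag_timer`, plus `step_index`.
#' @export
new_lattice <- function(rows, cols) {
  stopifnot(rows >= 1, cols >= 1)
  structure(list(species = matrix(0L, rows, cols),
                 is_lag = matrix(0L, rows, cols),
                 lag_timer = matrix(0L, rows, cols),
                 step_index = 0L),
            class = "ca_lattice")
}

#' @export
print.ca_lattice <- function(x, ...) {
  occ <- sum(x$species > 0)
  cat(sprintf("ca_lattice %d x %d (torus), step %d: %d occupied (%d in lag)\n",
              nrow(x$species), ncol(x$species), x$step_index, occ,
              sum(x$is_lag == 1)))
  invisible(x)
}

#' Randomly seed the initial lattice
#'
#' Places the initial cells uniformly at random without replacement over
#' all sites.  Each species targets `M` cells; the total is capped at
#' `max_fill * rows * cols` by proportional rescaling, and the cell budget
#' is split so collaborator cells make up fraction `M_p` of the total
#' (divided equally among the species of each role, largest-remainder
#' rounding).  All cells start active (`is_lag = 0`, timer 0).
#'
#' @param species A `species_table` from [sample_community()].
#' @param cfg A [community_config()].
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @param rescale Rescale counts to the capacity cap; with `rescale = FALSE`
#'   an over-capacity request is a configuration error instead.
#' @return A `ca_lattice` with the initial community placed.
#' @export
seed_lattice <- function(species, cfg, seed = NULL, rescale = TRUE) {
  stopifnot(nrow(species) >= 1)
  validate_config(cfg)
  if (!is.null(seed)) set.seed(seed)
  sites <- cfg$lattice_rows * cfg$lattice_cols
  cap <- floor(cfg$max_fill * sites)
  n_sp <- nrow(species)
  if (cap < n_sp)
    stop("configuration error: lattice capacity (", cap,
         " sites at max_fill) cannot hold one cell per species")
  target_total <- n_sp * cfg$M
  if (target_total > cap && !rescale)
    stop("configuration error: requested ", target_total,
         " cells exceed capacity ", cap)
  total <- min(target_total, cap)

  is_collab <- species$role == "collaborator"
  n_c <- sum(is_collab)
  n_s <- n_sp - n_c
  budget_c <- if (n_c == 0) 0 else if (n_s == 0) total else round(total * cfg$M_p)
  budget_s <- total - budget_c

  split_equally <- function(budget, k) {
    if (k == 0) return(integer(0))
    base <- rep(floor(budget / k), k)
    rem <- budget - sum(base)
    if (rem > 0) base[seq_len(rem)] <- base[seq_len(rem)] + 1L
    base
  }
  counts <- integer(n_sp)
  counts[is_collab] <- split_equally(budget_c, n_c)
  counts[!is_collab] <- split_equally(budget_s, n_s)
  if (sum(counts) > sites)
    stop("configuration error: occupancy request exceeds lattice size")

  lat <- new_lattice(cfg$lattice_rows, cfg$lattice_cols)
  pos <- sample.int(sites, sum(counts))
  lat$species[pos] <- rep.int(species$species_id, counts)
  lat
}

#' Export / import a species table as CSV
#'
#' @param species A `species_table`.
#' @param path File path.
#' @export
write_species_table <- function(species, path) {
  utils::write.csv(as.data.frame(species), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_species_table
#' @export
read_species_table <- function(path) {
  sp <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species_id", "role", .param_names)
  miss <- setdiff(need, names(sp))
  if (length(miss)) stop("species table missing columns: ",
                         paste(miss, collapse = ", "))
  class(sp) <- c("species_table", "data.frame")
  sp
}
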