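# R surface over the compiled CA core.  Species tables are converted once
# per call into the parallel vectors the C++ phases expect.

.species_arrays <- function(species) {
  n <- nrow(species)
  if (any(species$species_id != seq_len(n)))
    stop("species_id must be 1..N in order")
  list(role = as.integer(species$role == "collaborator"),
       aprob = as.matrix(species[, c("alpha1", "alpha2", "alpha3")]),
       bprob = as.matrix(species[, c("beta1", "beta2", "beta3")]),
       m = as.numeric(species$m), p = as.numeric(species$p),
       d = as.numeric(species$d), Lat = as.integer(species$Lat),
       nfac = as.integer(species$n))
}

.check_lattice <- function(lat) {
  stopifnot(inherits(lat, "ca_lattice"))
  invisible(lat)
}

#' Neighbourhood statistic MLL
#'
#' For an occupied focal site, counts the occupied Moore neighbours (8
#' torus-wrapped sites) whose behavioural role is opposite to the focal
#' cell's role: scammers around a collaborator, collaborators around a
#' scammer.  This is the statistic that selects the lag-entry probability
#' tier, encoding the decomposition-product feedback: a collaborator ringed
#' by scammers (public-good consumers) faces substrate depletion, a scammer
#' far from any collaborator (producer) faces substrate scarcity.
#' `literal = TRUE` instead sums the role flag of occupied neighbours (a
#' collaborator count for every focal cell), exposed for sensitivity checks.
#'
#' @param lat A `ca_lattice`.
#' @param i,j Focal site (1-based), which must be occupied.
#' @param species A `species_table`.
#' @param literal Use the same-type sum semantics.
#' @return Integer in `0..8`.
#' @export
mll <- function(lat, i, j, species, literal = FALSE) {
  .check_lattice(lat)
  if (lat$species[i, j] == 0) stop("focal site (", i, ",", j, ") is unoccupied")
  sa <- .species_arrays(species)
  m <- cpp_mll_matrix(lat$species, sa$role, literal)
  m[i, j]
}

#' @rdname mll
#' @return `mll_matrix` returns the full matrix (NA at vacant sites).
#' @export
mll_matrix <- function(lat, species, literal = FALSE) {
  .check_lattice(lat)
  sa <- .species_arrays(species)
  cpp_mll_matrix(lat$species, sa$role, literal)
}

#' Lag-entry probability for a species at a given MLL tier
#'
#' Collaborators use `alpha1/alpha2/alpha3` and scammers `beta1/beta2/beta3`
#' for MLL in 6--8, 3--5, 0--2 respectively.  Because
#' `alpha1 > alpha2 > alpha3` and `beta1 < beta2 < beta3`, more opposite
#' neighbours always mean a higher lag probability for collaborators and a
#' lower one for scammers.
#'
#' @param sp One species-table row.
#' @param mll_value Integer in `0..8`.
#' @return Probability in \[0, 1\].
#' @export
lag_tier_probability <- function(sp, mll_value) {
  if (!is.numeric(mll_value) || mll_value < 0 || mll_value > 8)
    stop("mll_value must lie in [0, 8]")
  tier <- if (mll_value >= 6) 1L else if (mll_value >= 3) 2L else 3L
  if (sp$role == "collaborator") c(sp$alpha1, sp$alpha2, sp$alpha3)[tier]
  else c(sp$beta1, sp$beta2, sp$beta3)[tier]
}

.unpack_phase <- function(lat, res, counter_names) {
  lat$species <- res$species
  lat$is_lag <- res$is_lag
  lat$lag_timer <- res$lag_timer
  attr(lat, "counts") <- unlist(res[counter_names])
  lat
}

#' CA update phases
#'
#' The three synchronous phases of one step, individually callable.
#' `apply_lag_rule` lets every active occupied cell enter the lag phase with
#' its tier probability (decided from the pre-phase snapshot).
#' `update_lag_and_death` ages lagged cells, applies the overrun death risk
#' `p` once `lag_timer > Lat * n`, recovers survivors with probability
#' `1/Lat`, then applies natural death `d` to every occupied cell.
#' `apply_move_rule` fills vacancies with offspring of occupied, non-lagged
#' cells from the radius-3 shell (48 candidates, torus), each volunteering
#' with its species' probability `m`; one offspring per parent per step.
#'
#' @param lat A `ca_lattice`.
#' @param species A `species_table`.
#' @param literal Literal MLL semantics (see [mll()]).
#' @return The updated lattice; phase event counts in `attr(, "counts")`.
#' @export
apply_lag_rule <- function(lat, species, literal = FALSE) {
  .check_lattice(lat)
  sa <- .species_arrays(species)
  res <- cpp_lag_phase(lat$species, lat$is_lag, lat$lag_timer,
                       sa$role, sa$aprob, sa$bprob, literal)
  .unpack_phase(lat, res, "lag_entries")
}

#' @rdname apply_lag_rule
#' @export
update_lag_and_death <- function(lat, species) {
  .check_lattice(lat)
  sa <- .species_arrays(species)
  res <- cpp_death_phase(lat$species, lat$is_lag, lat$lag_timer,
                         sa$p, sa$d, sa$Lat, sa$nfac)
  .unpack_phase(lat, res, c("recoveries", "overrun_deaths", "natural_deaths"))
}

#' @rdname apply_lag_rule
#' @export
apply_move_rule <- function(lat, species) {
  .check_lattice(lat)
  sa <- .species_arrays(species)
  res <- cpp_move_phase(lat$species, lat$is_lag, lat$lag_timer, sa$m)
  .unpack_phase(lat, res, "births")
}

#' Advance the lattice by one synchronous step
#'
#' Applies, in order, the lag-induction rule, the lag/death bookkeeping and
#' the move (proliferation) rule; increments `step_index`.  Fully
#' deterministic given the lattice, the species table and the RNG state.
#'
#' @inheritParams apply_lag_rule
#' @param lag_enabled `FALSE` skips the lag-induction phase (the no-delay
#'   null condition).
#' @return The lattice at `step_index + 1`; the per-step event counts
#'   (`lag_entries`, `recoveries`, `overrun_deaths`, `natural_deaths`,
#'   `births`) in `attr(, "counts")`.
#' @export
ca_step <- function(lat, species, lag_enabled = TRUE, literal = FALSE) {
  .check_lattice(lat)
  sa <- .species_arrays(species)
  res <- cpp_ca_step(lat$species, lat$is_lag, lat$lag_timer, sa$role,
                     sa$aprob, sa$bprob, sa$m, sa$p, sa$d, sa$Lat, sa$nfac,
                     literal, lag_enabled)
  lat <- .unpack_phase(lat, res, c("lag_entries", "recoveries",
                                   "overrun_deaths", "natural_deaths", "births"))
  lat$step_index <- lat$step_index + 1L
  lat
}

#' Run the cellular automaton
#'
#' Steps the lattice `steps` times, recording per-species population counts
#' at every step, the per-step event log, and strided lattice snapshots.
#'
#' @param lat Initial `ca_lattice` (see [seed_lattice()]).
#' @param species A `species_table`.
#' @param steps Number of steps.
#' @param snapshot_stride Keep a lattice snapshot every this many steps
#'   (step 0 and the final step are always kept); `0` keeps only those two.
#' @inheritParams ca_step
#' @return A list of class `ca_run`: `species`, `counts` (N x (steps+1)
#'   matrix, column `t` = populations after step `t`), `events` (data frame),
#'   `snapshots` (named list of lattices), `final` (final lattice).
#' @export
run_ca <- function(lat, species, steps, snapshot_stride = 10,
                   lag_enabled = TRUE, literal = FALSE) {
  .check_lattice(lat)
  n_sp <- nrow(species)
  counts <- matrix(0L, n_sp, steps + 1L,
                   dimnames = list(species$species_id, 0:steps))
  counts[, 1] <- cpp_species_counts(lat$species, n_sp)
  events <- data.frame(step = seq_len(steps), lag_entries = 0L, recoveries = 0L,
                       overrun_deaths = 0L, natural_deaths = 0L, births = 0L)
  snapshots <- list("0" = lat)
  for (t in seq_len(steps)) {
    lat <- ca_step(lat, species, lag_enabled = lag_enabled, literal = literal)
    counts[, t + 1L] <- cpp_species_counts(lat$species, n_sp)
    events[t, -1] <- as.integer(attr(lat, "counts"))
    if ((snapshot_stride > 0 && t %% snapshot_stride == 0) || t == steps)
      snapshots[[as.character(t)]] <- lat
  }
  structure(list(species = species, counts = counts, events = events,
                 snapshots = snapshots, final = lat),
            class = "ca_run")
}

#' @export
print.ca_run <- function(x, ...) {
  surv <- sum(x$counts[, ncol(x$counts)] > 0)
  cat(sprintf("ca_run: %d species, %d steps, %d snapshots; %d species surviving\n",
              nrow(x$counts), ncol(x$counts) - 1L, length(x$snapshots), surv))
  invisible(x)
}

#' Export lattice snapshots
#'
#' `write_snapshot` dumps the species-id matrix (-1 for vacant) as CSV;
#' `write_snapshot_png` renders the lattice with the species colours.
#'
#' @param lat A `ca_lattice`.
#' @param path Output file.
#' @export
write_snapshot <- function(lat, path) {
  m <- lat$species
  m[m == 0L] <- -1L
  utils::write.table(m, path, sep = ",", row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_snapshot
#' @param species A `species_table` supplying colours.
#' @export
write_snapshot_png <- function(lat, species, path) {
  pal <- c("#FFFFFF", species$color)
  cols <- matrix(pal[lat$species + 1L], nrow(lat$species), ncol(lat$species))
  grDevices::png(path, width = ncol(cols) * 4, height = nrow(cols) * 4)
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(grDevices::as.raster(cols), 0, 0, 1, 1,
                        interpolate = FALSE)
  invisible(path)
}
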