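test_that("MLL counts opposite-role Moore neighbours on the torus", {
  sp <- toy_species(n_collab = 1, n_scam = 1)
  lat <- new_lattice(9, 9)
  # focal collaborator at (5,5), all 8 neighbours scammers
  lat$species[5, 5] <- 1L
  for (di in -1:1) for (dj in -1:1)
    if (di || dj) lat$species[5 + di, 5 + dj] <- 2L
  expect_equal(mll(lat, 5, 5, sp), 8)
  expect_equal(mll(lat, 4, 4, sp), 1) # scammer sees 1 collaborator neighbour

  # all neighbours vacant
  lat2 <- new_lattice(9, 9)
  lat2$species[1, 1] <- 2L
  expect_equal(mll(lat2, 1, 1, sp), 0)

  # focal scammer with 3 collaborator, 2 scammer, 3 vacant neighbours
  lat3 <- new_lattice(9, 9)
  lat3$species[2, 2] <- 2L
  lat3$species[1, 1] <- 1L; lat3$species[1, 2] <- 1L; lat3$species[1, 3] <- 1L
  lat3$species[2, 1] <- 2L; lat3$species[3, 3] <- 2L
  expect_equal(mll(lat3, 2, 2, sp), 3)
  expect_equal(mll(lat3, 2, 2, sp), oracle_mll(lat3, sp, 2, 2))

  expect_error(mll(new_lattice(9, 9), 1, 1, sp), "unoccupied")
})

test_that("fast MLL equals the brute-force modular oracle on a full 9x9 torus", {
  set.seed(42)
  sp <- toy_species(n_collab = 2, n_scam = 2)
  lat <- new_lattice(9, 9)
  lat$species[] <- sample(0:4, 81, replace = TRUE)
  for (literal in c(FALSE, TRUE)) {
    fast <- mll_matrix(lat, sp, literal = literal)
    for (i in 1:9) for (j in 1:9) {
      if (lat$species[i, j] == 0) {
        expect_true(is.na(fast[i, j]))
      } else {
        expect_equal(fast[i, j], oracle_mll(lat, sp, i, j, literal),
                     info = sprintf("site (%d,%d) literal=%s", i, j, literal))
      }
    }
  }
})

test_that("lag tier probabilities follow the tier boundaries and orderings", {
  sp <- toy_species()
  collab <- sp[1, ]; scam <- sp[2, ]
  expect_equal(lag_tier_probability(collab, 7), collab$alpha1)
  expect_equal(lag_tier_probability(collab, 5), collab$alpha2)
  expect_equal(lag_tier_probability(collab, 0), collab$alpha3)
  expect_equal(lag_tier_probability(scam, 8), scam$beta1)
  expect_equal(lag_tier_probability(scam, 2), scam$beta3)
  expect_error(lag_tier_probability(collab, 9), "\\[0, 8\\]")
  # monotone in the opposite-neighbour count
  pc <- sapply(0:8, function(k) lag_tier_probability(collab, k))
  ps <- sapply(0:8, function(k) lag_tier_probability(scam, k))
  expect_true(all(diff(pc) >= 0))
  expect_true(all(diff(ps) <= 0))
})

test_that("lag rule obeys degenerate probabilities and binomial expectation", {
  # all tier probabilities 0 -> nobody lags; 1 -> every active cell lags
  mk <- function(alpha) {
    sp <- toy_species(alpha = alpha, beta = alpha)
    lat <- new_lattice(10, 10)
    lat$species[] <- sample(1:2, 100, replace = TRUE)
    list(sp = sp, lat = lat)
  }
  set.seed(1)
  z <- mk(c(0, 0, 0))
  expect_equal(sum(apply_lag_rule(z$lat, z$sp)$is_lag), 0)
  o <- mk(c(1, 1, 1) - c(0, 1e-9, 2e-9)) # strictly ordered, ~1
  expect_equal(sum(apply_lag_rule(o$lat, o$sp)$is_lag), 100)

  # isolated collaborators ringed by 8 scammers: entry fraction ~ alpha1
  sp <- toy_species(alpha = c(0.8, 0.5, 0.1))
  lat <- new_lattice(100, 100)
  lat$species[] <- 2L
  ci <- seq(1, 100, by = 4)
  lat$species[ci, ci] <- 1L # 625 isolated collaborators, MLL = 8
  set.seed(99)
  entered <- replicate(16, {
    out <- apply_lag_rule(lat, sp)
    sum(out$is_lag[ci, ci])
  })
  frac <- sum(entered) / (625 * 16)
  expect_equal(frac, 0.8, tolerance = 0.02 / 0.8)
})

test_that("lag bookkeeping: overrun death threshold, recovery, natural death", {
  # deterministic overrun: p = 1, recovery impossible only if still lagged;
  # with Lat = 6, n = 1 the p-check begins once the timer exceeds 6
  sp <- toy_species(p = 1, d = 0, Lat = 6L, n = 1L)
  lat <- new_lattice(8, 8)
  lat$species[4, 4] <- 1L
  lat$is_lag[4, 4] <- 1L
  lat$lag_timer[4, 4] <- 5L
  set.seed(2)
  out <- update_lag_and_death(lat, sp)
  # timer became 6, not > 6: no overrun death possible this step
  expect_equal(attr(out, "counts")[["overrun_deaths"]], 0L)
  expect_equal(out$species[4, 4], 1L)
  lat$lag_timer[4, 4] <- 6L
  deaths <- replicate(64, {
    o <- update_lag_and_death(lat, sp)
    attr(o, "counts")[["overrun_deaths"]]
  })
  expect_equal(sum(deaths), 64) # timer 7 > 6, p = 1: always dies

  # d = 1 empties the lattice in one step
  spd <- toy_species(d = 1)
  full <- new_lattice(8, 8)
  full$species[] <- 1L
  expect_equal(sum(update_lag_and_death(full, spd)$species), 0)

  # no removal or addition channels: occupancy conserved
  spq <- toy_species(alpha = c(0, 0, 0), beta = c(0, 0, 0), m = 0, p = 0, d = 0)
  spq$alpha1 <- 3e-9; spq$alpha2 <- 2e-9; spq$alpha3 <- 1e-9
  spq$beta1 <- 1e-9; spq$beta2 <- 2e-9; spq$beta3 <- 3e-9
  spq$p <- 1e-9; spq$d <- 0
  lat0 <- new_lattice(10, 10)
  lat0$species[1:5, 1:5] <- 1L
  cur <- lat0
  for (k in 1:5) cur <- ca_step(cur, spq)
  expect_equal(sum(cur$species > 0), 25)
})

test_that("move rule: 48-candidate shell, degenerate m, single parent", {
  # a vacancy on a >= 7x7 torus has exactly 48 candidate positions
  offs <- expand.grid(di = -3:3, dj = -3:3)
  offs <- offs[!(offs$di == 0 & offs$dj == 0), ]
  expect_equal(nrow(offs), 48)

  sp0 <- toy_species(m = 0, d = 0, alpha = c(0, 0, 0), beta = c(0, 0, 0))
  sp0$alpha1 <- 3e-9; sp0$alpha2 <- 2e-9; sp0$alpha3 <- 1e-9
  sp0$beta1 <- 1e-9; sp0$beta2 <- 2e-9; sp0$beta3 <- 3e-9
  lat <- new_lattice(10, 10)
  lat$species[2, 2] <- 1L
  set.seed(3)
  out <- apply_move_rule(lat, sp0)
  expect_equal(sum(out$species > 0), 1) # m = 0: no vacancy ever filled

  sp1 <- sp0
  sp1$m <- 1
  out1 <- apply_move_rule(lat, sp1)
  # sole occupied cell with m = 1: parents exactly one offspring per step
  expect_equal(sum(out1$species > 0), 2)
  expect_equal(attr(out1, "counts")[["births"]], 1)

  # lagged cells are not move-rule parents
  latl <- lat
  latl$is_lag[2, 2] <- 1L
  outl <- apply_move_rule(latl, sp1)
  expect_equal(attr(outl, "counts")[["births"]], 0)
})

test_that("step composition: empty lattice, identity parameters, determinism", {
  sp <- toy_species()
  empty <- new_lattice(9, 9)
  set.seed(4)
  out <- ca_step(empty, sp)
  expect_equal(sum(out$species), 0)
  expect_equal(out$step_index, 1L)

  cfg <- community_config(N = 6, N_p = 0.5, M = 30, lattice_rows = 20,
                          lattice_cols = 20, steps = 0, seed = 10)
  pool <- sample_community(cfg)
  lat <- seed_lattice(pool, cfg)
  run1 <- {
    set.seed(11)
    cur <- lat
    for (k in 1:10) cur <- ca_step(cur, pool)
    cur
  }
  run2 <- {
    set.seed(11)
    cur <- lat
    for (k in 1:10) cur <- ca_step(cur, pool)
    cur
  }
  expect_identical(run1$species, run2$species)
  expect_identical(run1$is_lag, run2$is_lag)
  expect_identical(run1$lag_timer, run2$lag_timer)
})

test_that("occupancy bookkeeping identity holds exactly at every step", {
  cfg <- community_config(N = 8, N_p = 0.5, M = 40, lattice_rows = 30,
                          lattice_cols = 30, steps = 0, seed = 21)
  pool <- sample_community(cfg)
  lat <- seed_lattice(pool, cfg)
  set.seed(22)
  occ <- sum(lat$species > 0)
  for (k in 1:30) {
    lat <- ca_step(lat, pool)
    cnt <- attr(lat, "counts")
    occ_new <- sum(lat$species > 0)
    expect_identical(
      occ_new,
      occ - as.integer(cnt[["overrun_deaths"]] + cnt[["natural_deaths"]]) +
        as.integer(cnt[["births"]]))
    occ <- occ_new
  }
})
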