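# Independent oracles and small fixture builders used across the suite.

# brute-force torus Moore neighbourhood by modular arithmetic
oracle_moore_neighbors <- function(i, j, R, C) {
  out <- matrix(NA_integer_, 8, 2)
  k <- 0
  for (di in -1:1) for (dj in -1:1) {
    if (di == 0 && dj == 0) next
    k <- k + 1
    out[k, ] <- c((i - 1 + di) %% R + 1, (j - 1 + dj) %% C + 1)
  }
  out
}

# brute-force opposite-role neighbour count
oracle_mll <- function(lat, species, i, j, literal = FALSE) {
  nb <- oracle_moore_neighbors(i, j, nrow(lat$species), ncol(lat$species))
  focal <- lat$species[i, j]
  role <- function(id) species$role[species$species_id == id]
  cnt <- 0
  for (k in 1:8) {
    s <- lat$species[nb[k, 1], nb[k, 2]]
    if (s == 0) next
    if (literal) cnt <- cnt + as.integer(role(s) == "collaborator")
    else if (role(s) != role(focal)) cnt <- cnt + 1
  }
  cnt
}

# cophenetic distance of a leaf pair from an hclust tree, by walking the
# merge table and returning the height of the first merge joining them
oracle_cophenetic <- function(hc, a, b) {
  sets <- vector("list", nrow(hc$merge))
  get_set <- function(x) if (x < 0) -x else sets[[x]]
  for (k in seq_len(nrow(hc$merge))) {
    s1 <- get_set(hc$merge[k, 1])
    s2 <- get_set(hc$merge[k, 2])
    sets[[k]] <- c(s1, s2)
    if ((a %in% s1 && b %in% s2) || (a %in% s2 && b %in% s1))
      return(hc$height[k])
  }
  NA_real_
}

# a small fully specified species table (no RNG) for engine tests
toy_species <- function(n_collab = 1, n_scam = 1,
                        alpha = c(0.9, 0.5, 0.1), beta = c(0.1, 0.5, 0.9),
                        m = 0.1, p = 0.9, d = 0.2, Lat = 6L, n = 1L) {
  n_sp <- n_collab + n_scam
  df <- data.frame(
    species_id = seq_len(n_sp),
    role = c(rep("collaborator", n_collab), rep("scammer", n_scam)),
    alpha1 = alpha[1], alpha2 = alpha[2], alpha3 = alpha[3],
    beta1 = beta[1], beta2 = beta[2], beta3 = beta[3],
    m = m, p = p, d = d, Lat = Lat, n = n,
    stringsAsFactors = FALSE)
  df$color <- "#000000"
  class(df) <- c("species_table", "data.frame")
  df
}

# place cells on an empty lattice: cells = matrix/list of (i, j, species_id)
place_cells <- function(lat, cells) {
  for (k in seq_len(nrow(cells)))
    lat$species[cells[k, 1], cells[k, 2]] <- as.integer(cells[k, 3])
  lat
}

param_cols <- c("alpha1", "alpha2", "alpha3", "beta1", "beta2", "beta3",
                "m", "p", "d", "Lat", "n")
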