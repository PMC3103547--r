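# Shared fixtures, all generated in code.

# A straight-ish chain of the given residue types built from the package's
# ideal-geometry templates (no turn).
make_chain <- function(seq3, chain_id = "A") {
  n <- length(seq3)
  lib <- load_rotamer_library()
  at <- satmut:::.build_chain(chain_id, seq3, rep(-120, n), rep(130, n), lib)
  new_structure(at)
}

# Free "ions": one single-atom residue per row of pos. No bonds, so every
# pair is nonbonded at full weight. Parameters are set directly.
ion_structure <- function(pos, q, sigma = 3.5, epsilon = 0, gbr = 2,
                          chain = "C", element = "C") {
  n <- nrow(pos)
  atoms <- data.frame(
    chain = rep(chain, length.out = n), resno = seq_len(n), insert = "",
    resid = "ION", elety = "X", elesy = element,
    x = pos[, 1], y = pos[, 2], z = pos[, 3], het = FALSE,
    charge = rep(q, length.out = n), sigma = rep(sigma, length.out = n),
    epsilon = rep(epsilon, length.out = n), gbr = rep(gbr, length.out = n),
    stringsAsFactors = FALSE)
  # allow several chains
  atoms$resno <- stats::ave(seq_len(n), atoms$chain, FUN = seq_along)
  new_structure(atoms)
}

# Minimal parameter set for ion fixtures: CAT carries +1, ANI -1, NEU 0.
# With es = ei the GB term vanishes; with epsilon = 0 the LJ term vanishes.
ion_forcefield <- function(eps_int = 1, eps_solv = 1, lj_eps = 0,
                           sigma = 3.5, gbr = 2) {
  p <- list(name = "ion_test",
            charges = data.frame(
              resid = c("CAT", "ANI", "NEU"), elety = "X",
              charge = c(1, -1, 0), class = "C",
              stringsAsFactors = FALSE),
            classes = data.frame(class = "C", sigma = sigma,
                                 epsilon = lj_eps, gb_radius = gbr,
                                 stringsAsFactors = FALSE),
            interior_dielectric = eps_int, solvent_dielectric = eps_solv)
  class(p) <- "ForceFieldParams"
  p
}

# Two-chain salt bridge: +1 in chain C, -1 in chain D at distance r.
salt_bridge_dimer <- function(r = 3.32) {
  atoms <- data.frame(
    chain = c("C", "D"), resno = 1L, insert = "",
    resid = c("CAT", "ANI"), elety = "X", elesy = "C",
    x = c(0, r), y = 0, z = 0, het = FALSE,
    charge = NA_real_, sigma = NA_real_, epsilon = NA_real_, gbr = NA_real_,
    stringsAsFactors = FALSE)
  new_structure(atoms)
}

# Cached toy dimer shared across test files (built once per test run).
toy_cache <- new.env(parent = emptyenv())
get_toy_dimer <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(toy_cache[[key]])) {
    toy_cache[[key]] <- build_toy_dimer(toy_spec(seed = seed))
  }
  toy_cache[[key]]
}

# Population standard deviation (oracle for profile checks).
pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
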