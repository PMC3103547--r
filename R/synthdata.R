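# synthdata: deterministic generators for the structures, titration systems
# and effect tables the analysis is exercised on. The toy protein is a
# two-chain beta-hairpin sandwich: each chain packs two extended strands
# through a sharp turn, and the second chain stacks against the first so that
# one face forms a non-symmetric dimer interface. Three site archetypes are
# placed: a solvent-exposed turn site (Gly), an interface site (Val) facing
# the partner chain, and a buried site (Ile) in the packed core layer.

#' Specification for the toy dimer
#'
#' @param n_residues residues per chain (default 22: strand, 3-residue turn,
#'   strand).
#' @param interface_offset inter-chain stacking distance, A.
#' @param interface_shift along-strand shift of chain D, A (makes the
#'   interface non-symmetric).
#' @param loop_site,interface_site,buried_site residue numbers of the three
#'   archetype sites.
#' @param decorations data.frame (resno, aa) of residue replacements applied
#'   to both chains (acidic/basic pocket construction).
#' @param seed integer seed (mandatory); controls the small coordinate jitter
#'   that keeps fixtures from being pathologically symmetric.
#' @param jitter coordinate jitter standard deviation, A.
#' @return a \code{ToySpec}.
#' @export
toy_spec <- function(n_residues = 22L, interface_offset = 12.2,
                     interface_shift = 1.7, loop_site = 11L,
                     interface_site = 15L, buried_site = 7L,
                     decorations = NULL, seed = 1L, jitter = 0.02) {
  if (is.null(seed)) stop("seed is mandatory")
  stopifnot(n_residues >= 16)
  sites <- c(loop_site, interface_site, buried_site)
  if (any(sites < 1 | sites > n_residues)) stop("site outside chain range")
  out <- list(n_residues = as.integer(n_residues),
              interface_offset = interface_offset,
              interface_shift = interface_shift,
              loop_site = as.integer(loop_site),
              interface_site = as.integer(interface_site),
              buried_site = as.integer(buried_site),
              decorations = decorations, seed = as.integer(seed),
              jitter = jitter)
  class(out) <- "ToySpec"
  out
}

# default residue identities: hydrophobic strands, Gly at the turn site,
# Val at the interface, Ile in the core, acidic residues next to the buried
# site and the turn (negative-potential micro-environments), one basic and a
# few polar residues for the titration machinery
.toy_sequence <- function(spec) {
  n <- spec$n_residues
  seq3 <- rep(c("ALA", "LEU", "VAL", "ALA"), length.out = n)
  seq3[2] <- "LYS"
  seq3[4] <- "ASP"
  seq3[8] <- "GLU"
  seq3[9] <- "SER"
  seq3[10] <- "ASN"
  seq3[min(n, 12)] <- "THR"
  seq3[min(n, 13)] <- "ASP"
  seq3[min(n, 21)] <- "GLU"
  seq3[spec$loop_site] <- "GLY"
  seq3[spec$interface_site] <- "VAL"
  seq3[spec$buried_site] <- "ILE"
  if (!is.null(spec$decorations)) {
    for (k in seq_len(nrow(spec$decorations))) {
      seq3[spec$decorations$resno[k]] <- toupper(spec$decorations$aa[k])
    }
  }
  seq3
}

# phi/psi profile: two packed strands joined by a chain-reversing turn at the
# loop site. The torsions are a fixed "ideal turn" template chosen at design
# time so that the two strands pack at 5-8 A with no hard clashes.
.toy_torsions <- function(spec) {
  n <- spec$n_residues
  phi <- rep(-255.3, n); psi <- rep(148.2, n)
  t0 <- spec$loop_site
  psi[t0 - 1] <- -53.6
  phi[t0]     <- 206.3
  psi[t0]     <- -36.4
  phi[t0 + 1] <- -223.5
  list(phi = phi, psi = psi)
}

# assemble one chain (atom data.frame) from sequence + torsions + rotamers
.build_chain <- function(chain_id, seq3, phi, psi, lib) {
  bb <- build_backbone(phi, psi)
  rows <- list()
  for (i in seq_along(seq3)) {
    aa <- seq3[i]
    r <- bb[[i]]
    atoms <- data.frame(
      chain = chain_id, resno = i, insert = "", resid = aa,
      elety = c("N", "CA", "C", "O"), elesy = c("N", "C", "C", "O"),
      x = c(r$N[1], r$CA[1], r$C[1], r$O[1]),
      y = c(r$N[2], r$CA[2], r$C[2], r$O[2]),
      z = c(r$N[3], r$CA[3], r$C[3], r$O[3]),
      het = FALSE, stringsAsFactors = FALSE)
    nchi <- N_CHI[[aa]]
    chi <- if (nchi > 0) lib[[aa]][1, seq_len(nchi)] else numeric(0)
    sc <- build_sidechain(aa, r, chi)
    if (length(sc) > 0) {
      atoms <- rbind(atoms, data.frame(
        chain = chain_id, resno = i, insert = "", resid = aa,
        elety = names(sc), elesy = attr(sc, "elements"),
        x = vapply(sc, `[`, numeric(1), 1),
        y = vapply(sc, `[`, numeric(1), 2),
        z = vapply(sc, `[`, numeric(1), 3),
        het = FALSE, stringsAsFactors = FALSE))
    }
    rows[[i]] <- atoms
  }
  do.call(rbind, rows)
}

#' Build the synthetic toy dimer
#'
#' Deterministic for a given spec (including its seed). Chains are labelled C
#' and D; chain D is the 180-degree-rotated copy of chain C stacked at
#' \code{interface_offset} and shifted by \code{interface_shift} along the
#' strands, so the interface is not symmetric.
#'
#' @param spec a \code{ToySpec}.
#' @return a two-chain \code{Structure}.
#' @export
build_toy_dimer <- function(spec = toy_spec()) {
  stopifnot(inherits(spec, "ToySpec"))
  lib <- load_rotamer_library()
  seq3 <- .toy_sequence(spec)
  tor <- .toy_torsions(spec)
  ac <- .build_chain("C", seq3, tor$phi, tor$psi, lib)
  # chain D: translated copy stacked against the lower face of chain C; the
  # two faces in contact differ, so the homodimer interface is not symmetric
  ad <- ac
  ad$chain <- "D"
  ad$z <- ad$z - spec$interface_offset
  ad$x <- ad$x + spec$interface_shift
  atoms <- rbind(ac, ad)
  set.seed(spec$seed)
  if (spec$jitter > 0) {
    atoms$x <- atoms$x + stats::rnorm(nrow(atoms), 0, spec$jitter)
    atoms$y <- atoms$y + stats::rnorm(nrow(atoms), 0, spec$jitter)
    atoms$z <- atoms$z + stats::rnorm(nrow(atoms), 0, spec$jitter)
  }
  s <- new_structure(atoms, title = "synthetic toy dimer",
                     numbering_offset = 0L)
  # deterministic greedy rotamer cleanup: each residue keeps the library
  # rotamer with the lowest clash score
  n <- spec$n_residues
  for (ch in c("C", "D")) {
    for (i in seq_len(n)) {
      aa <- seq3[i]
      nchi <- N_CHI[[aa]]
      if (nchi == 0) next
      rots <- lib[[aa]]
      scs <- vapply(seq_len(nrow(rots)), function(k)
        clash_score(set_sidechain(s, ch, i, aa, rots[k, seq_len(nchi)]),
                    ch, i), numeric(1))
      s <- set_sidechain(s, ch, i, aa, rots[which.min(scs), seq_len(nchi)])
    }
  }
  # reject overlapping chains
  cr <- clash_report(s, scale = 0.5)
  if (nrow(cr) > 0) {
    stop("chains overlap (", nrow(cr),
         " hard clashes); increase interface_offset")
  }
  attr(s, "spec") <- spec
  s
}

#' Neighbour-count burial proxy
#'
#' Number of heavy atoms (any chain) within \code{radius} A of the residue's
#' side-chain centroid (CA for Gly), excluding the residue's own atoms. The
#' toy generator documents >= 45 as "buried".
#'
#' @param s a \code{Structure}.
#' @param chain_id,resno the residue.
#' @param radius neighbourhood radius, A (default 8).
#' @return integer neighbour count.
#' @export
burial_count <- function(s, chain_id, resno, radius = 8) {
  rows <- residue_rows(s, chain_id, resno)
  nm <- s$atoms$elety[rows]
  sc <- rows[!(nm %in% BACKBONE_ATOMS)]
  ref_rows <- if (length(sc) > 0) sc else rows[match("CA", nm)]
  xyz <- coords(s)
  ref <- colMeans(xyz[ref_rows, , drop = FALSE])
  d <- sqrt(colSums((t(xyz) - ref)^2))
  sum(d <= radius) - length(rows[d[rows] <= radius])
}

#' Minimum inter-chain distance from one residue
#'
#' @param s a two-chain \code{Structure}.
#' @param chain_id,resno the residue.
#' @return minimum distance (A) from the residue's atoms to any atom of the
#'   other chain.
#' @export
interchain_min_dist <- function(s, chain_id, resno) {
  rows <- residue_rows(s, chain_id, resno)
  other <- which(s$atoms$chain != chain_id & !s$atoms$het)
  xyz <- coords(s)
  min(vapply(rows, function(i)
    min(sqrt(colSums((t(xyz[other, , drop = FALSE]) - xyz[i, ])^2))),
    numeric(1)))
}

#' Coulomb electrostatic potential at a site
#'
#' Unscreened Coulomb potential (eps = 1) at the residue's side-chain
#' centroid (CA for Gly) from all partial charges outside the residue, in
#' kcal/(mol e).
#'
#' @param s a parameterized \code{Structure}.
#' @param chain_id,resno the site.
#' @return potential in kcal/(mol e).
#' @export
site_potential <- function(s, chain_id, resno) {
  .check_param(s)
  rows <- residue_rows(s, chain_id, resno)
  nm <- s$atoms$elety[rows]
  sc <- rows[!(nm %in% BACKBONE_ATOMS)]
  ref_rows <- if (length(sc) > 0) sc else rows[match("CA", nm)]
  xyz <- coords(s)
  ref <- colMeans(xyz[ref_rows, , drop = FALSE])
  others <- setdiff(seq_len(nrow(xyz)), rows)
  d <- sqrt(colSums((t(xyz[others, , drop = FALSE]) - ref)^2))
  sum(KE_COULOMB * s$atoms$charge[others] / d)
}

#' Decorate the neighbourhood of a site with charged residues
#'
#' Replaces up to \code{n_acids} residues whose CA lies within 10 A of the
#' site (nearest first, the site itself and Gly/Pro excluded) by residues
#' cycled from \code{aa_pool}, using the standard mutation machinery. With
#' the default acidic pool the Coulomb potential at the site becomes strictly
#' negative.
#'
#' @param s a \code{Structure}.
#' @param around list/row with chain and resno of the focal site.
#' @param n_acids number of residues to replace.
#' @param aa_pool replacement residue types (default Asp/Glu).
#' @param radius candidate search radius, A.
#' @return decorated \code{Structure}.
#' @export
build_negative_pocket <- function(s, around, n_acids,
                                  aa_pool = c("ASP", "GLU"), radius = 10) {
  if (n_acids == 0) return(s)
  lib <- load_rotamer_library()
  rt <- residue_table(s)
  xyz <- coords(s)
  ca_of <- function(ch, rn) {
    rows <- residue_rows(s, ch, rn)
    rows[match("CA", s$atoms$elety[rows])]
  }
  focal <- xyz[ca_of(around$chain, around$resno), ]
  cand <- rt[!(rt$chain == around$chain & rt$resno == around$resno), ]
  cand <- cand[!(cand$resid %in% c("GLY", "PRO")), ]
  dd <- vapply(seq_len(nrow(cand)), function(k)
    sqrt(sum((xyz[ca_of(cand$chain[k], cand$resno[k]), ] - focal)^2)),
    numeric(1))
  cand <- cand[dd <= radius, , drop = FALSE]
  dd <- dd[dd <= radius]
  cand <- cand[order(dd), , drop = FALSE]
  cand <- cand[!(cand$resid %in% aa_pool), , drop = FALSE]
  if (nrow(cand) < n_acids) {
    stop("not enough candidate residues within ", radius, " A (have ",
         nrow(cand), ", need ", n_acids, ")")
  }
  for (k in seq_len(n_acids)) {
    aa <- aa_pool[(k - 1) %% length(aa_pool) + 1]
    s <- mutate_residue(s, mutation_spec(cand$chain[k], cand$resno[k],
                                         aa), lib)
  }
  s
}

#' Random titration-system fixture
#'
#' @param n_sites number of titratable sites (<= 20 for enumeration oracles).
#' @param coupling_scale couplings drawn as |N(0, coupling_scale)| kcal/mol;
#'   0 gives independent sites.
#' @param seed integer seed (mandatory).
#' @return a \code{TitrationSystem} with random model pKas in [3, 12].
#' @export
make_titration_fixture <- function(n_sites, coupling_scale = 0.5, seed) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  set.seed(seed)
  aa <- sample(names(MODEL_PKAS), n_sites, replace = TRUE)
  sites <- data.frame(chain = "C", resno = seq_len(n_sites), insert = "",
                      resid = aa, model_pka = stats::runif(n_sites, 3, 12),
                      ionized_charge = SITE_CHARGE[aa],
                      stringsAsFactors = FALSE)
  sites$intrinsic_pka <- sites$model_pka
  W <- matrix(0, n_sites, n_sites)
  if (coupling_scale > 0 && n_sites > 1) {
    ut <- upper.tri(W)
    W[ut] <- abs(stats::rnorm(sum(ut), 0, coupling_scale))
    W <- W + t(W)
  }
  new_titration_system(sites, W)
}

# archetype regime targets for the energy metrics: population mean and sd the
# sampled 19-vector is affinely standardized to
.EFFECT_REGIMES <- list(
  g56  = list(folding = c(mean = 2.2,  sd = 3.8),
              binding = c(mean = -4.9, sd = 4.4)),
  v132 = list(folding = c(mean = 0.3,  sd = 6.2),
              binding = c(mean = 3.0,  sd = 4.9)),
  i150 = list(folding = c(mean = -6.5, sd = 5.2),
              binding = c(mean = 0.0,  sd = 1.6))
)

.WT_OF_ARCHETYPE <- c(g56 = "G", v132 = "V", i150 = "I")

#' Sample a 19-substitution effect table for a site archetype
#'
#' Draws a 19-vector shaped like the archetype's qualitative regime (bulk of
#' small effects plus archetype-specific tails) and, for the energy metrics,
#' affinely standardizes it to the regime's population mean and standard
#' deviation, so the mean/HSTD relations that drive classification hold for
#' essentially every seed. The pka metric returns non-negative cumulative
#' shift magnitudes and is not standardized.
#'
#' @param archetype "g56" (exposed turn), "v132" (interface) or "i150"
#'   (buried core).
#' @param metric "folding", "binding" or "pka".
#' @param seed integer seed (mandatory).
#' @return named numeric vector of 19 effects (names: substitution one-letter
#'   codes, wild type excluded).
#' @export
effect_table_fixture <- function(archetype = c("g56", "v132", "i150"),
                                 metric = c("folding", "binding", "pka"),
                                 seed) {
  archetype <- match.arg(archetype)
  metric <- match.arg(metric)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  set.seed(seed)
  ru <- function(n, a, b) stats::runif(n, a, b)
  x <- switch(paste(archetype, metric),
    # exposed turn: most substitutions near zero, Lys/Arg/Tyr-like strong
    # stabilizers push the mean just past the HSTD threshold
    "g56 folding"  = c(ru(12, -0.5, 1.0), ru(3, 3, 5), ru(4, 8, 10)),
    # periphery-of-interface: most substitutions weaken binding
    "g56 binding"  = c(ru(6, -2, 0), ru(1, 0.5, 1.5), ru(10, -8, -4),
                       ru(2, -17, -13)),
    "g56 pka"      = c(ru(15, 0, 0.6), ru(4, 2.4, 3.2)),
    # interface pocket: near-zero mean with charged outliers of both signs
    "v132 folding" = c(ru(13, -1, 1), ru(3, -10, -8), ru(3, 8, 10)),
    "v132 binding" = c(ru(12, -1, 0.5), ru(4, 8, 10), ru(1, 5, 7),
                       ru(2, -7, -5)),
    "v132 pka"     = c(ru(15, 0, 0.4), ru(4, 2.2, 3.0)),
    # buried core: almost everything destabilizes, charged residues worst;
    # the mildest substitutions are merely neutral, never favourable
    "i150 folding" = c(ru(2, -16, -14), ru(13, -9, -3), ru(4, -1.5, 0)),
    "i150 binding" = ru(19, -1, 1),
    "i150 pka"     = c(ru(13, 1.5, 3.5), ru(6, 3.5, 6))
  )
  x <- sample(x)  # shuffle which substitution gets which regime component
  if (metric != "pka") {
    tgt <- .EFFECT_REGIMES[[archetype]][[metric]]
    mu <- mean(x)
    sdev <- sqrt(sum((x - mu)^2) / length(x))
    x <- (x - mu) / sdev * tgt[["sd"]] + tgt[["mean"]]
  }
  names(x) <- sort(setdiff(AA1, .WT_OF_ARCHETYPE[[archetype]]))
  x
}
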