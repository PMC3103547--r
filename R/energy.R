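# energy: simplified molecular-mechanics potential. LJ + Coulomb over a
# bond-separation-masked pair list and Still Generalized-Born solvation with
# HCT pairwise-descreening Born radii (descreening scale 0.8). Nonbonded
# exclusions follow the usual convention on the global bond graph (peptide
# bonds included): 1-2 and 1-3 pairs excluded, 1-4 pairs scaled by 0.5, no
# cutoff. Torsion-space side-chain relaxation stands in for full Cartesian
# minimization; the 0.01 kcal/mol convergence tolerance is interpreted as the
# minimal energy improvement per sweep.

KE_COULOMB <- 332.0636   # kcal*A/(mol*e^2)
GB_DESCREEN <- 0.8       # HCT descreening scale factor

# Global bond list (atom row-index pairs): intra-residue topology bonds plus
# peptide C(i)-N(i+1) bonds between consecutive residues of a chain.
bond_list <- function(s) {
  a <- s$atoms
  out_i <- integer(0); out_j <- integer(0)
  rt <- residue_table(s)
  prev_c <- NA_integer_; prev_chain <- ""
  for (k in seq_len(nrow(rt))) {
    rows <- residue_rows(s, rt$chain[k], rt$resno[k])
    nm <- a$elety[rows]
    aa <- rt$resid[k]
    if (aa %in% AA3) {
      for (b in residue_bonds(aa)) {
        i <- rows[match(b[1], nm)]; j <- rows[match(b[2], nm)]
        if (!is.na(i) && !is.na(j)) { out_i <- c(out_i, i); out_j <- c(out_j, j) }
      }
    }
    ni <- rows[match("N", nm)]
    ci <- rows[match("C", nm)]
    if (!is.na(prev_c) && identical(prev_chain, rt$chain[k]) && !is.na(ni)) {
      out_i <- c(out_i, prev_c); out_j <- c(out_j, ni)
    }
    prev_c <- if (is.na(ci)) NA_integer_ else ci
    prev_chain <- rt$chain[k]
  }
  cbind(out_i, out_j)
}

# Masked nonbonded pair list: all atom pairs except 1-2/1-3 (dropped) with
# 1-4 pairs down-weighted 0.5. Returns list(i, j, w) with 0-based indices for
# the C++ kernel.
nonbonded_pairs <- function(s) {
  n <- nrow(s$atoms)
  if (n < 2) return(list(i = integer(0), j = integer(0), w = numeric(0)))
  W <- matrix(1, n, n)
  bl <- bond_list(s)
  if (nrow(bl) > 0) {
    # sparse bond-graph powers: the bond graph has O(n) edges, so the
    # separation-<=2 and separation-<=3 patterns stay sparse
    A <- Matrix::sparseMatrix(i = pmin(bl[, 1], bl[, 2]),
                              j = pmax(bl[, 1], bl[, 2]),
                              x = 1, dims = c(n, n), symmetric = TRUE)
    B <- A + A %*% A        # bond separation <= 2 (diagonal included)
    C <- B + B %*% A        # bond separation <= 3
    tc <- Matrix::mat2triplet(C)
    off <- tc$i != tc$j
    W[cbind(tc$i[off], tc$j[off])] <- 0.5
    tb <- Matrix::mat2triplet(B)
    off <- tb$i != tb$j
    W[cbind(tb$i[off], tb$j[off])] <- 0
  }
  ut <- upper.tri(W)
  keep <- ut & W > 0
  idx <- which(keep, arr.ind = TRUE)
  list(i = idx[, 1] - 1L, j = idx[, 2] - 1L, w = W[keep])
}

# Internal: full parameter check.
.check_param <- function(s) {
  if (anyNA(s$atoms$charge) || anyNA(s$atoms$sigma) || anyNA(s$atoms$gbr)) {
    stop("structure not parameterized; call assign_parameters() first")
  }
}

#' Effective Born radii (HCT pairwise descreening)
#'
#' @param s a parameterized \code{Structure}.
#' @return numeric vector of effective Born radii, one per atom (A).
#' @export
born_radii <- function(s) {
  .check_param(s)
  born_radii_cpp(coords(s), s$atoms$gbr, GB_DESCREEN)
}

#' Nonbonded energy terms
#'
#' \code{coulomb_energy} and \code{lj_energy} sum over the masked nonbonded
#' pair list; \code{gb_energy} is the Still Generalized-Born solvation energy
#' over all atom pairs (self terms included).
#'
#' @param s a parameterized \code{Structure}.
#' @param eps_int,eps_solv interior and solvent dielectric constants.
#' @param pairs optional precomputed pair list from
#'   \code{nonbonded_pairs()} (reused during relaxation).
#' @return energy in kcal/mol.
#' @export
coulomb_energy <- function(s, eps_int = 1.0, eps_solv = 78.5, pairs = NULL) {
  energy_terms(s, eps_int, eps_solv, pairs)$coulomb
}

#' @rdname coulomb_energy
#' @export
lj_energy <- function(s, eps_int = 1.0, eps_solv = 78.5, pairs = NULL) {
  energy_terms(s, eps_int, eps_solv, pairs)$lj
}

#' @rdname coulomb_energy
#' @export
gb_energy <- function(s, eps_int = 1.0, eps_solv = 78.5, pairs = NULL) {
  energy_terms(s, eps_int, eps_solv, pairs)$gb
}

# All three terms in one kernel call.
energy_terms <- function(s, eps_int = 1.0, eps_solv = 78.5, pairs = NULL) {
  .check_param(s)
  if (is.null(pairs)) pairs <- nonbonded_pairs(s)
  xyz <- coords(s)
  born <- born_radii_cpp(xyz, s$atoms$gbr, GB_DESCREEN)
  nb_energy_cpp(xyz, s$atoms$charge, s$atoms$sigma, s$atoms$epsilon, born,
                pairs$i, pairs$j, pairs$w, eps_int, eps_solv)
}

#' Total potential energy with breakdown
#'
#' @param s a \code{Structure} (parameterized or not).
#' @param p a \code{ForceFieldParams}; when given, parameters are (re)assigned
#'   before evaluation and its dielectrics are used.
#' @return an \code{EnergyBreakdown} list with lj, coulomb, gb and total
#'   (kcal/mol), total = lj + coulomb + gb.
#' @export
total_energy <- function(s, p = NULL) {
  ei <- 1.0; es <- 78.5
  if (!is.null(p)) {
    s <- assign_parameters(s, p)
    ei <- p$interior_dielectric; es <- p$solvent_dielectric
  }
  t <- energy_terms(s, ei, es)
  out <- list(lj = t$lj, coulomb = t$coulomb, gb = t$gb,
              total = t$lj + t$coulomb + t$gb)
  class(out) <- "EnergyBreakdown"
  out
}

#' @export
print.EnergyBreakdown <- function(x, ...) {
  cat(sprintf("EnergyBreakdown (kcal/mol): LJ %.4f  Coulomb %.4f  GB %.4f  total %.4f\n",
              x$lj, x$coulomb, x$gb, x$total))
  invisible(x)
}

# Current chi angles of a residue measured from coordinates (NA when a chi
# atom is missing).
measure_chis <- function(s, chain_id, resno) {
  aa <- residue_aa(s, chain_id, resno)
  nchi <- N_CHI[[aa]]
  if (nchi == 0) return(numeric(0))
  rows <- residue_rows(s, chain_id, resno)
  nm <- s$atoms$elety[rows]
  getp <- function(atom) {
    r <- rows[match(atom, nm)]
    if (is.na(r)) return(NULL)
    as.numeric(s$atoms[r, c("x", "y", "z")])
  }
  topo <- SIDECHAIN_TOPOLOGY[[aa]]
  chis <- rep(NA_real_, nchi)
  for (row in topo) {
    if (!is.na(row$chi) && row$dih == 0 && is.na(chis[row$chi])) {
      A <- getp(row$dref); B <- getp(row$aref); C <- getp(row$parent)
      D <- getp(row$name)
      if (!is.null(A) && !is.null(B) && !is.null(C) && !is.null(D)) {
        chis[row$chi] <- torsion(A, B, C, D)
      }
    }
  }
  chis
}

# Replace the side-chain coordinates of one residue with an ideal-geometry
# rebuild at the given chi angles. Backbone atoms never move. Atom rows for
# the side chain are regenerated (old side chain dropped).
set_sidechain <- function(s, chain_id, resno, aa = NULL, chi = numeric(0)) {
  rows <- residue_rows(s, chain_id, resno)
  if (length(rows) == 0) stop("no residue ", resno, " in chain ", chain_id)
  if (is.null(aa)) aa <- s$atoms$resid[rows[1]]
  check_backbone(s, chain_id, resno)
  a <- s$atoms
  nm <- a$elety[rows]
  bb <- list(
    N = as.numeric(a[rows[match("N", nm)], c("x", "y", "z")]),
    CA = as.numeric(a[rows[match("CA", nm)], c("x", "y", "z")]),
    C = as.numeric(a[rows[match("C", nm)], c("x", "y", "z")]))
  sc <- build_sidechain(aa, bb, chi)
  keep_rows <- rows[nm %in% BACKBONE_ATOMS]
  drop_rows <- setdiff(rows, keep_rows)
  bb_block <- a[keep_rows, , drop = FALSE]
  bb_block$resid <- aa
  if (length(sc) > 0) {
    sc_block <- data.frame(
      chain = chain_id, resno = resno, insert = bb_block$insert[1],
      resid = aa, elety = names(sc),
      elesy = attr(sc, "elements"),
      x = vapply(sc, `[`, numeric(1), 1),
      y = vapply(sc, `[`, numeric(1), 2),
      z = vapply(sc, `[`, numeric(1), 3),
      het = FALSE, charge = NA_real_, sigma = NA_real_,
      epsilon = NA_real_, gbr = NA_real_, stringsAsFactors = FALSE)
    block <- rbind(bb_block, sc_block)
  } else {
    block <- bb_block
  }
  before <- a[seq_len(min(rows) - 1L), , drop = FALSE]
  after_rows <- setdiff(seq_len(nrow(a)), c(rows, seq_len(min(rows) - 1L)))
  after <- a[after_rows, , drop = FALSE]
  s$atoms <- rbind(before, block, after)
  rownames(s$atoms) <- NULL
  s
}

#' Torsion-space side-chain relaxation
#'
#' Coordinate descent over the chi angles of the scope residues with the
#' backbone fixed. Each chi is moved to the best of a deterministic candidate
#' set; sweeps stop when a full sweep improves the total energy by less than
#' \code{tol} (default 0.01 kcal/mol) or after \code{max_sweeps}. The returned
#' structure never has higher energy than the input.
#'
#' @param s a \code{Structure}.
#' @param p a \code{ForceFieldParams}.
#' @param scope data.frame with columns chain and resno selecting the side
#'   chains allowed to move (default: all residues).
#' @param tol convergence tolerance, kcal/mol.
#' @param max_sweeps sweep cap; non-convergence returns best-so-far with
#'   attribute \code{converged = FALSE}.
#' @return relaxed \code{Structure} with attributes \code{energy} (an
#'   \code{EnergyBreakdown}) and \code{converged}.
#' @export
relax <- function(s, p, scope = NULL, tol = 0.01, max_sweeps = 20L) {
  s <- assign_parameters(s, p)
  ei <- p$interior_dielectric; es <- p$solvent_dielectric
  rt <- residue_table(s)
  if (is.null(scope)) scope <- rt[, c("chain", "resno")]
  # residues with at least one chi
  scope_aa <- as.character(mapply(function(ch, rn) residue_aa(s, ch, rn),
                                  scope$chain, scope$resno))
  movable <- which(N_CHI[scope_aa] > 0)
  converged <- TRUE
  if (length(movable) > 0 && is.finite(tol)) {
    # canonicalize movable side chains to ideal internal geometry at their
    # measured chi angles so the atom order (and hence the pair mask) is
    # stable across chi trials
    for (k in movable) {
      chis <- measure_chis(s, scope$chain[k], scope$resno[k])
      if (anyNA(chis)) next
      s <- set_sidechain(s, scope$chain[k], scope$resno[k], scope_aa[k], chis)
    }
    s <- assign_parameters(s, p)
    pairs <- nonbonded_pairs(s)
    a <- s$atoms
    xyz <- coords(s)
    # fast path: chi trials only patch the side-chain rows of one residue in
    # the coordinate matrix; metadata and the pair mask never change
    res_info <- lapply(movable, function(k) {
      ch <- scope$chain[k]; rn <- scope$resno[k]; aa <- scope_aa[k]
      rows <- residue_rows(s, ch, rn)
      nm <- a$elety[rows]
      bb <- list(N = xyz[rows[match("N", nm)], ],
                 CA = xyz[rows[match("CA", nm)], ],
                 C = xyz[rows[match("C", nm)], ])
      sc_names <- sidechain_atom_names(aa)
      sc_rows <- rows[match(sc_names, nm)]
      chis <- measure_chis(s, ch, rn)
      list(aa = aa, bb = bb, sc_rows = sc_rows, chis = chis)
    })
    eval_total <- function(xyz) {
      nb_total_cpp(xyz, a$charge, a$sigma, a$epsilon, a$gbr, GB_DESCREEN,
                   pairs$i, pairs$j, pairs$w, ei, es)
    }
    patch <- function(xyz, info, chi) {
      sc <- build_sidechain(info$aa, info$bb, chi)
      xyz[info$sc_rows, ] <- do.call(rbind, sc)
      xyz
    }
    e_now <- eval_total(xyz)
    deltas <- c(-120, -60, -30, -10, 10, 30, 60, 120, 180)
    converged <- FALSE
    for (sweep in seq_len(max_sweeps)) {
      e_start <- e_now
      for (k in seq_along(res_info)) {
        info <- res_info[[k]]
        if (anyNA(info$chis) || anyNA(info$sc_rows)) next
        for (ci in seq_along(info$chis)) {
          best_e <- e_now; best_chi <- info$chis; improved <- FALSE
          for (d in deltas) {
            trial <- info$chis; trial[ci] <- info$chis[ci] + d
            e2 <- eval_total(patch(xyz, info, trial))
            if (e2 < best_e - 1e-12) {
              best_e <- e2; best_chi <- trial; improved <- TRUE
            }
          }
          if (improved) {
            info$chis <- best_chi
            xyz <- patch(xyz, info, best_chi)
            res_info[[k]] <- info
            e_now <- best_e
          }
        }
      }
      if (e_start - e_now < tol) { converged <- TRUE; break }
    }
    s$atoms$x <- xyz[, 1]; s$atoms$y <- xyz[, 2]; s$atoms$z <- xyz[, 3]
  }
  attr(s, "energy") <- total_energy(s, p)
  attr(s, "converged") <- converged
  s
}
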