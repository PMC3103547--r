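# titration: continuum-electrostatics pKa machinery. Titratable sites get an
# intrinsic pKa (model pKa + Born-desolvation and background-charge shifts),
# pairwise ionized-ionized couplings are computed with the screened
# Coulomb/GB interaction, and ionization microstates are Boltzmann-averaged
# either exactly (enumeration, <= 20 sites) or by single-site Metropolis
# Monte Carlo. pKa(1/2) is the pH where the protonation fraction crosses 0.5.

PK_KCAL <- 1.364          # kcal/mol per pK unit at 298 K
KT_KCAL <- PK_KCAL / log(10)  # 0.5924 kcal/mol

MODEL_PKAS <- c(ASP = 4.0, GLU = 4.4, HIS = 6.3, LYS = 10.4, ARG = 12.0,
                TYR = 9.6, CYS = 8.3)
SITE_CHARGE <- c(ASP = -1, GLU = -1, HIS = +1, LYS = +1, ARG = +1,
                 TYR = -1, CYS = -1)
# representative charged-group atom per titratable residue type
SITE_ATOM <- c(ASP = "CG", GLU = "CD", HIS = "NE2", LYS = "NZ", ARG = "CZ",
               TYR = "OH", CYS = "SG")

#' Locate titratable sites in a structure
#'
#' @param s a \code{Structure}.
#' @param aa_set 3-letter codes treated as titratable.
#' @return data.frame of sites ordered by (chain, residue number) with model
#'   pKa and ionized charge.
#' @export
find_titratable <- function(s, aa_set = names(MODEL_PKAS)) {
  rt <- residue_table(s)
  rt <- rt[rt$resid %in% aa_set, , drop = FALSE]
  rt <- rt[order(rt$chain, rt$resno), , drop = FALSE]
  rt$model_pka <- MODEL_PKAS[rt$resid]
  rt$ionized_charge <- SITE_CHARGE[rt$resid]
  rownames(rt) <- NULL
  rt
}

# Effective Born radius of one site's representative atom within structure s
# and for the residue extracted alone (the solvent-exposed reference).
.site_born <- function(s, chain_id, resno) {
  aa <- residue_aa(s, chain_id, resno)
  atom <- SITE_ATOM[[aa]]
  rows <- residue_rows(s, chain_id, resno)
  irow <- rows[match(atom, s$atoms$elety[rows])]
  if (is.na(irow)) stop("site ", chain_id, resno, " lacks atom ", atom)
  B_all <- born_radii(s)
  alone <- new_structure(s$atoms[rows, , drop = FALSE],
                         numbering_offset = s$numbering_offset)
  B_ref <- born_radii(alone)[match(irow, rows)]
  list(row = irow, B = B_all[irow], B_ref = B_ref, all = B_all)
}

#' Intrinsic pKa of a titratable site
#'
#' Model pKa shifted by the Born-desolvation penalty of the ionized form
#' (relative to the fully exposed residue alone) and by the screened
#' interaction with background (non-titratable) charges; site-site coupling
#' is excluded here and handled by the titration engine.
#'
#' @param site one row of \code{find_titratable()} output (or a list with
#'   chain, resno).
#' @param s a parameterized \code{Structure}.
#' @param p a \code{ForceFieldParams}.
#' @return intrinsic pKa (pK units).
#' @export
intrinsic_pka <- function(site, s, p) {
  .check_param(s)
  aa <- residue_aa(s, site$chain, site$resno)
  q <- SITE_CHARGE[[aa]]
  acid <- q < 0
  sb <- .site_born(s, site$chain, site$resno)
  ei <- p$interior_dielectric; es <- p$solvent_dielectric
  tau <- 1 / ei - 1 / es
  # desolvation of the unit charge: GB self-energy in context minus exposed
  dg_desolv <- -0.5 * tau * KE_COULOMB * (1 / sb$B - 1 / sb$B_ref)
  # background interaction: site unit charge vs charges of non-titratable
  # residues (side chains and all backbones), GB-screened
  a <- s$atoms
  titr <- find_titratable(s)
  titr_key <- paste(titr$chain, titr$resno)
  own <- residue_rows(s, site$chain, site$resno)
  bg <- which(!a$het & !(seq_len(nrow(a)) %in% own) &
                !(paste(a$chain, a$resno) %in% titr_key &
                    !(a$elety %in% BACKBONE_ATOMS)))
  dg_bg <- 0
  if (length(bg) > 0) {
    idx <- c(sb$row, bg)
    qv <- c(q, a$charge[bg])
    W <- screened_coupling_cpp(coords(s)[idx, , drop = FALSE], qv,
                               sb$all[idx], ei, es)
    dg_bg <- sum(W[1, -1])
  }
  sign <- if (acid) +1 else -1
  unname(MODEL_PKAS[[aa]] + sign * (dg_desolv + dg_bg) / PK_KCAL)
}

#' Build a titration system from a structure
#'
#' @param s a parameterized \code{Structure}.
#' @param p a \code{ForceFieldParams}.
#' @param aa_set titratable residue types.
#' @return a \code{TitrationSystem}: sites table (with intrinsic pKas) and
#'   symmetric coupling matrix W (kcal/mol) between ionized forms.
#' @export
build_titration_system <- function(s, p, aa_set = names(MODEL_PKAS)) {
  .check_param(s)
  sites <- find_titratable(s, aa_set)
  n <- nrow(sites)
  if (n == 0) return(new_titration_system(sites, matrix(0, 0, 0)))
  sb <- lapply(seq_len(n), function(k) .site_born(s, sites$chain[k], sites$resno[k]))
  sites$intrinsic_pka <- vapply(seq_len(n), function(k)
    intrinsic_pka(sites[k, ], s, p), numeric(1))
  idx <- vapply(sb, `[[`, numeric(1), "row")
  born <- vapply(sb, `[[`, numeric(1), "B")
  W <- screened_coupling_cpp(coords(s)[idx, , drop = FALSE],
                             sites$ionized_charge, born,
                             p$interior_dielectric, p$solvent_dielectric)
  new_titration_system(sites, W)
}

#' Construct a TitrationSystem directly
#'
#' @param sites data.frame with columns chain, resno, resid, model_pka,
#'   ionized_charge and intrinsic_pka (missing intrinsic pKas default to the
#'   model values).
#' @param W symmetric coupling matrix, kcal/mol, zero diagonal.
#' @return a \code{TitrationSystem}.
#' @export
new_titration_system <- function(sites, W) {
  n <- nrow(sites)
  if (is.null(sites$intrinsic_pka)) sites$intrinsic_pka <- sites$model_pka
  W <- as.matrix(W)
  stopifnot(nrow(W) == n, ncol(W) == n)
  if (n > 0) {
    if (max(abs(W - t(W))) > 1e-9) stop("coupling matrix not symmetric")
    if (max(abs(diag(W))) > 1e-12) stop("coupling matrix diagonal not zero")
  }
  out <- list(sites = sites, W = W, pk_kcal = PK_KCAL)
  class(out) <- "TitrationSystem"
  out
}

#' @export
print.TitrationSystem <- function(x, ...) {
  cat(sprintf("TitrationSystem: %d sites, max |coupling| %.3f kcal/mol\n",
              nrow(x$sites),
              if (nrow(x$sites) > 1) max(abs(x$W)) else 0))
  invisible(x)
}

# Energy of the ionized form of each site at a given pH (kcal/mol):
# acids favour ionization above their pKa, bases below.
.site_field <- function(sys, ph) {
  acid <- sys$sites$ionized_charge < 0
  ifelse(acid,
         PK_KCAL * (sys$sites$intrinsic_pka - ph),
         PK_KCAL * (ph - sys$sites$intrinsic_pka))
}

#' Titration curves of a coupled system
#'
#' Boltzmann averages of per-site protonation over ionization microstates,
#' with state energy \code{sum_i x_i h_i(pH) + sum_{i<j} x_i x_j W_ij}.
#' \code{method = "enumerate"} sums all 2^n states (n <= 20);
#' \code{method = "monte_carlo"} uses single-site Metropolis flips.
#'
#' @param sys a \code{TitrationSystem}.
#' @param ph_grid pH values.
#' @param method "enumerate" or "monte_carlo".
#' @param seed RNG seed (required for Monte Carlo).
#' @param sweeps MC sweeps per pH point (default 1e4; 1e5 for oracle-grade
#'   accuracy).
#' @param burn_frac fraction of sweeps discarded as burn-in.
#' @return matrix (length(ph_grid) x n sites) of protonation fractions, pH as
#'   rownames.
#' @export
titration_curve <- function(sys, ph_grid = seq(0, 14, by = 0.1),
                            method = c("enumerate", "monte_carlo"),
                            seed = NULL, sweeps = 10000L, burn_frac = 0.1) {
  method <- match.arg(method)
  n <- nrow(sys$sites)
  out <- matrix(NA_real_, length(ph_grid), n)
  rownames(out) <- format(ph_grid)
  colnames(out) <- paste0(sys$sites$chain, sys$sites$resno)
  if (n == 0) return(out)
  acid <- sys$sites$ionized_charge < 0
  if (method == "enumerate") {
    if (n > 20) stop("enumeration limited to 20 sites; use method='monte_carlo'")
    states <- as.matrix(expand.grid(rep(list(0:1), n)))
    pair_e <- rowSums((states %*% sys$W) * states) / 2
    for (k in seq_along(ph_grid)) {
      h <- .site_field(sys, ph_grid[k])
      E <- as.vector(states %*% h) + pair_e
      w <- exp(-(E - min(E)) / KT_KCAL)
      x_mean <- colSums(states * w) / sum(w)
      out[k, ] <- ifelse(acid, 1 - x_mean, x_mean)
    }
  } else {
    if (is.null(seed)) stop("monte_carlo titration requires a seed")
    set.seed(seed)
    for (k in seq_along(ph_grid)) {
      h <- .site_field(sys, ph_grid[k])
      x_mean <- mc_titration_cpp(h, sys$W, as.integer(sweeps), burn_frac,
                                 KT_KCAL)
      out[k, ] <- ifelse(acid, 1 - x_mean, x_mean)
    }
  }
  out
}

#' Compute pKa(1/2) values for every titratable site of a structure
#'
#' @param s a parameterized \code{Structure}.
#' @param p a \code{ForceFieldParams}.
#' @param method titration engine (enumeration by default, switching to
#'   Monte Carlo automatically above 20 sites).
#' @param seed RNG seed for Monte Carlo.
#' @param ph_grid pH grid (default 0-14 step 0.1).
#' @param sweeps MC sweeps per pH point.
#' @return data.frame: chain, resno, resid, model/intrinsic pKa, pka (pH of
#'   the first 0.5 protonation crossing, linearly interpolated; < min(grid)
#'   and > max(grid) reported as -1/15 sentinels with \code{out_of_range}),
#'   plus \code{nonmonotonic} flag.
#' @export
compute_pkas <- function(s, p, method = NULL, seed = 1L,
                         ph_grid = seq(0, 14, by = 0.1), sweeps = 10000L) {
  sys <- build_titration_system(s, p)
  compute_pkas_system(sys, method = method, seed = seed, ph_grid = ph_grid,
                      sweeps = sweeps)
}

#' @rdname compute_pkas
#' @param sys a \code{TitrationSystem} (alternative entry point).
#' @export
compute_pkas_system <- function(sys, method = NULL, seed = 1L,
                                ph_grid = seq(0, 14, by = 0.1),
                                sweeps = 10000L) {
  n <- nrow(sys$sites)
  if (is.null(method)) method <- if (n <= 20) "enumerate" else "monte_carlo"
  curves <- titration_curve(sys, ph_grid, method, seed = seed, sweeps = sweeps)
  out <- sys$sites
  out$pka <- NA_real_
  out$out_of_range <- FALSE
  out$nonmonotonic <- FALSE
  for (j in seq_len(n)) {
    f <- curves[, j]
    cross <- which(diff(sign(f - 0.5)) != 0)
    if (length(cross) == 0) {
      out$out_of_range[j] <- TRUE
      out$pka[j] <- if (f[1] < 0.5) min(ph_grid) - 1 else max(ph_grid) + 1
      next
    }
    if (length(cross) > 1) out$nonmonotonic[j] <- TRUE
    k <- cross[1]
    f1 <- f[k]; f2 <- f[k + 1]
    out$pka[j] <- ph_grid[k] + (0.5 - f1) / (f2 - f1) *
      (ph_grid[k + 1] - ph_grid[k])
  }
  out
}

#' pKa shift report between wild type and mutant (cumulative metric)
#'
#' Pairs sites by (chain, residue number, residue type); the per-site shift
#' is pKa(mutant) - pKa(wild type) and the cumulative metric is the sum of
#' absolute shifts over all paired sites. Sites present in only one context
#' (e.g. a titratable residue added or removed by the mutation itself) are
#' excluded from the sum and counted in the report.
#'
#' @param wt_pkas,mut_pkas outputs of \code{compute_pkas}.
#' @return a \code{PkaShiftReport}: per-site shifts, sum_abs, n_sites,
#'   n_unpaired.
#' @export
pka_shift_report <- function(wt_pkas, mut_pkas) {
  kw <- paste(wt_pkas$chain, wt_pkas$resno, wt_pkas$resid)
  km <- paste(mut_pkas$chain, mut_pkas$resno, mut_pkas$resid)
  common <- intersect(kw, km)
  if (length(common) == 0) stop("no paired titratable sites between WT and mutant")
  iw <- match(common, kw); im <- match(common, km)
  shifts <- mut_pkas$pka[im] - wt_pkas$pka[iw]
  per_site <- data.frame(chain = wt_pkas$chain[iw], resno = wt_pkas$resno[iw],
                         resid = wt_pkas$resid[iw],
                         pka_wt = wt_pkas$pka[iw], pka_mut = mut_pkas$pka[im],
                         dpka = shifts, stringsAsFactors = FALSE)
  out <- list(per_site = per_site, sum_abs = sum(abs(shifts)),
              n_sites = length(common),
              n_unpaired = length(kw) + length(km) - 2 * length(common))
  class(out) <- "PkaShiftReport"
  out
}

#' @export
print.PkaShiftReport <- function(x, ...) {
  cat(sprintf("PkaShiftReport: %d paired sites, sum |dpKa| = %.3f (%d unpaired)\n",
              x$n_sites, x$sum_abs, x$n_unpaired))
  invisible(x)
}

#' Flag monomer-vs-dimer ionization-state discrepancies
#'
#' A site is flagged when its ionized fraction at the given pH (from the
#' Henderson-Hasselbalch relation on the computed pKa) differs between the
#' monomer and dimer contexts by more than 0.5 -- e.g. a His analogue ionized
#' in the monomer but neutral in the dimer.
#'
#' @param monomer_pkas,dimer_pkas outputs of \code{compute_pkas} for the two
#'   contexts.
#' @param site list/row with chain and resno identifying the site.
#' @param ph comparison pH (default physiological 7.0).
#' @return list with both pKas, both ionized fractions and \code{flag}.
#' @export
flag_ionization_discrepancy <- function(monomer_pkas, dimer_pkas, site,
                                        ph = 7.0) {
  pick <- function(tab, what) {
    k <- which(tab$chain == site$chain & tab$resno == site$resno)
    if (length(k) == 0) stop("site not titratable in ", what, " context")
    tab[k[1], ]
  }
  m <- pick(monomer_pkas, "monomer")
  d <- pick(dimer_pkas, "dimer")
  ion_frac <- function(row) {
    if (row$ionized_charge < 0) 1 / (1 + 10^(row$pka - ph))
    else 1 / (1 + 10^(ph - row$pka))
  }
  fm <- ion_frac(m); fd <- ion_frac(d)
  list(chain = site$chain, resno = site$resno, resid = m$resid,
       pka_monomer = m$pka, pka_dimer = d$pka,
       ionized_monomer = fm, ionized_dimer = fd, ph = ph,
       flag = abs(fm - fd) > 0.5)
}
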