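# thermo: folding and binding free-energy change protocols with parameter-set
# and chain averaging.
#
# Binding: dG_bind = G(dimer) - G(C) - G(D), monomers taken rigid from the
# dimer (no re-relaxation); the mutation effect is the mutant-minus-wild-type
# difference of dG_bind, so the mutation-independent entropy of dimerization
# cancels. Folding: dG_fold = G(folded monomer) - G(segment), the segment
# being an odd-length window centred at the site extracted with coordinates
# unchanged; the remainder of the unfolded-state energy is mutation
# independent and drops out of differences. With potential energies,
# more-negative = more stable, so effect = mut - WT is negative when the
# mutation destabilizes, matching the reporting convention.

#' Binding free energy of a dimer (rigid-body protocol)
#'
#' @param dimer a two-chain \code{Structure}, already relaxed.
#' @param p a \code{ForceFieldParams}.
#' @return a \code{BindingResult} with g_dimer, g_c, g_d and
#'   dg_bind = g_dimer - g_c - g_d (kcal/mol, exact identity).
#' @export
binding_energy <- function(dimer, p) {
  mons <- split_monomers(dimer)
  g_dimer <- total_energy(dimer, p)$total
  g_c <- total_energy(mons[[1]], p)$total
  g_d <- total_energy(mons[[2]], p)$total
  out <- list(g_dimer = g_dimer, g_c = g_c, g_d = g_d,
              dg_bind = g_dimer - g_c - g_d,
              chains = names(mons))
  class(out) <- "BindingResult"
  out
}

#' @export
print.BindingResult <- function(x, ...) {
  cat(sprintf("BindingResult (kcal/mol): G(dimer)=%.4f G(%s)=%.4f G(%s)=%.4f dG_bind=%.4f\n",
              x$g_dimer, x$chains[1], x$g_c, x$chains[2], x$g_d, x$dg_bind))
  invisible(x)
}

#' Effect of a mutation on binding affinity
#'
#' Mean over parameter sets of dG_bind(mutant) - dG_bind(wild type).
#' Negative = the mutation weakens the dimer (set \code{flip_sign = TRUE} for
#' the opposite convention).
#'
#' @param wt,mut wild-type and mutant dimers, identically prepared.
#' @param param_sets list of \code{ForceFieldParams}.
#' @param flip_sign flip the reporting sign convention.
#' @return mean effect (kcal/mol) with per-set values in attribute
#'   \code{per_ff}.
#' @export
binding_effect <- function(wt, mut, param_sets = default_forcefields(),
                           flip_sign = FALSE) {
  if (!identical(chain_ids(wt), chain_ids(mut))) {
    stop("wild type and mutant have mismatched chains")
  }
  per_ff <- vapply(param_sets, function(p) {
    binding_energy(mut, p)$dg_bind - binding_energy(wt, p)$dg_bind
  }, numeric(1))
  names(per_ff) <- vapply(param_sets, `[[`, character(1), "name")
  out <- mean(per_ff)
  if (flip_sign) { out <- -out; per_ff <- -per_ff }
  attr(out, "per_ff") <- per_ff
  out
}

#' Folding free energy of a monomer (segment unfolded-state model)
#'
#' @param monomer single-chain \code{Structure}, already relaxed.
#' @param site residue number of the mutation site (segment centre).
#' @param seg_len odd segment length in [5, 9] (default 7).
#' @param p a \code{ForceFieldParams}.
#' @return a \code{FoldingResult} with g_folded, g_seg,
#'   dg_fold = g_folded - g_seg (the mutation-independent unfolded-state
#'   constant is dropped) and segment_length.
#' @export
folding_energy <- function(monomer, site, seg_len = 7L, p) {
  ids <- chain_ids(monomer)
  if (length(ids) != 1) stop("folding_energy expects a single-chain monomer")
  seg <- extract_segment(monomer, ids, site, seg_len)
  g_folded <- total_energy(monomer, p)$total
  g_seg <- total_energy(seg, p)$total
  out <- list(g_folded = g_folded, g_seg = g_seg,
              dg_fold = g_folded - g_seg,
              segment_length = n_residues(seg))
  class(out) <- "FoldingResult"
  out
}

#' @export
print.FoldingResult <- function(x, ...) {
  cat(sprintf("FoldingResult (kcal/mol): G(folded)=%.4f G_seg(unfolded)=%.4f dG_fold=%.4f (segment %d)\n",
              x$g_folded, x$g_seg, x$dg_fold, x$segment_length))
  invisible(x)
}

#' Effect of a mutation on monomer stability
#'
#' Mean over parameter sets (and over the supplied wild-type/mutant monomer
#' pairs, one per chain) of dG_fold(mutant) - dG_fold(wild type). Negative =
#' destabilizing.
#'
#' @param wt,mut single monomers or lists of monomers (one per chain),
#'   identically prepared.
#' @param site residue number of the site.
#' @param seg_len segment length.
#' @param param_sets list of \code{ForceFieldParams}.
#' @param flip_sign flip the reporting sign convention.
#' @return mean effect (kcal/mol); attributes \code{per_ff} (chain-averaged,
#'   per set) and \code{per_chain} (set-averaged, per chain).
#' @export
folding_effect <- function(wt, mut, site, seg_len = 7L,
                           param_sets = default_forcefields(),
                           flip_sign = FALSE) {
  if (inherits(wt, "Structure")) wt <- list(wt)
  if (inherits(mut, "Structure")) mut <- list(mut)
  if (length(wt) != length(mut)) stop("wt and mut monomer lists differ in length")
  m <- matrix(NA_real_, nrow = length(wt), ncol = length(param_sets))
  for (ci in seq_along(wt)) {
    for (fi in seq_along(param_sets)) {
      p <- param_sets[[fi]]
      m[ci, fi] <- folding_energy(mut[[ci]], site, seg_len, p)$dg_fold -
        folding_energy(wt[[ci]], site, seg_len, p)$dg_fold
    }
  }
  if (flip_sign) m <- -m
  out <- mean(m)
  per_ff <- colMeans(m)
  names(per_ff) <- vapply(param_sets, `[[`, character(1), "name")
  attr(out, "per_ff") <- per_ff
  attr(out, "per_chain") <- rowMeans(m)
  out
}

# Residues (chain, resno) with any atom within `radius` A of the site's
# atoms; includes the site itself.
relax_scope <- function(s, chain_id, resno, radius = 6) {
  xyz <- coords(s)
  site_rows <- residue_rows(s, chain_id, resno)
  d2min <- rep(Inf, nrow(xyz))
  for (i in site_rows) {
    d2 <- colSums((t(xyz) - xyz[i, ])^2)
    d2min <- pmin(d2min, d2)
  }
  hit <- d2min <= radius^2 & !s$atoms$het
  rt <- unique(s$atoms[hit, c("chain", "resno")])
  rownames(rt) <- NULL
  rt
}

#' Saturation scan of one site with energy (and optional pKa) effects
#'
#' For each of the 19 substitutions the site is mutated in each chain of the
#' relaxed wild-type dimer; the mutant dimer is relaxed (scope = mutated
#' residue plus residues within \code{relax_radius}) under each parameter
#' set, the binding effect is computed per placement and the folding effect
#' per chain from the rigid-split monomers, and results are averaged over
#' chains and parameter sets. Per-mutation failures are recorded, not fatal.
#'
#' @param dimer a two-chain \code{Structure} (wild type, unrelaxed is fine;
#'   it is relaxed once per parameter set with the same scope protocol).
#' @param site residue number of the site (present in both chains).
#' @param param_sets list of \code{ForceFieldParams}.
#' @param seg_len folding segment length (odd, default 7).
#' @param relax_radius relaxation scope radius around the site (A).
#' @param relax_sweeps sweep cap per relaxation.
#' @param lib rotamer library.
#' @param include_pka also run titration on every monomer and report the
#'   cumulative absolute pKa shift per mutation.
#' @param ph_grid pH grid for titration.
#' @param flip_sign flip the sign convention of both effects.
#' @param targets one-letter codes to scan (default: all 19 non-wild-type
#'   amino acids); the wild type is always excluded.
#' @return data.frame with one row per substitution: aa, ddg_fold, dddg_bind,
#'   per-set columns, sum_dpka (NA unless \code{include_pka}), ok, note.
#' @export
scan_site <- function(dimer, site, param_sets = default_forcefields(),
                      seg_len = 7L, relax_radius = 5, lib = NULL,
                      include_pka = FALSE, ph_grid = seq(0, 14, by = 0.1),
                      flip_sign = FALSE, relax_sweeps = 4L, targets = NULL) {
  stopifnot(inherits(dimer, "Structure"))
  if (is.null(lib)) lib <- load_rotamer_library()
  chains <- chain_ids(dimer)
  if (length(chains) != 2) stop("scan_site expects a two-chain dimer")
  wt_aa <- residue_aa(dimer, chains[1], site)
  if (is.null(targets)) targets <- AA1
  targets <- sort(setdiff(unique(toupper(targets)), AA1[[wt_aa]]))
  if (!all(targets %in% AA1)) {
    stop("non-canonical targets: ", paste(setdiff(targets, AA1), collapse = ", "))
  }
  ffnames <- vapply(param_sets, `[[`, character(1), "name")

  # one relaxed WT dimer per parameter set; scope = union of the site's
  # neighbourhood in both chains, applied identically to every mutant
  scopes <- lapply(chains, function(ch) relax_scope(dimer, ch, site, relax_radius))
  scope_all <- unique(do.call(rbind, scopes))
  wt_relaxed <- lapply(param_sets, function(p)
    relax(dimer, p, scope_all, max_sweeps = relax_sweeps))
  names(wt_relaxed) <- ffnames
  wt_bind <- mapply(function(s, p) binding_energy(s, p), wt_relaxed, param_sets,
                    SIMPLIFY = FALSE)
  wt_fold <- mapply(function(s, p) {
    mons <- split_monomers(s)
    lapply(mons, function(m) folding_energy(m, site, seg_len, p)$dg_fold)
  }, wt_relaxed, param_sets, SIMPLIFY = FALSE)

  wt_pkas <- NULL
  if (include_pka) {
    p1 <- param_sets[[1]]
    wt_pkas <- lapply(split_monomers(wt_relaxed[[1]]), function(m)
      compute_pkas(assign_parameters(m, p1), p1, ph_grid = ph_grid))
  }

  rows <- list()
  for (t1 in targets) {
    ddg_f <- matrix(NA_real_, length(chains), length(param_sets))
    ddd_b <- matrix(NA_real_, length(chains), length(param_sets))
    sum_dpka <- rep(NA_real_, length(chains))
    ok <- TRUE; note <- ""
    for (ci in seq_along(chains)) {
      res <- tryCatch({
        spec <- mutation_spec(chains[ci], site, t1)
        for (fi in seq_along(param_sets)) {
          p <- param_sets[[fi]]
          mut <- mutate_residue(wt_relaxed[[fi]], spec, lib)
          mutr <- relax(mut, p, scope_all, max_sweeps = relax_sweeps)
          b <- binding_energy(mutr, p)
          ddd_b[ci, fi] <- b$dg_bind - wt_bind[[fi]]$dg_bind
          mons <- split_monomers(mutr)
          ddg_f[ci, fi] <- folding_energy(mons[[ci]], site, seg_len, p)$dg_fold -
            wt_fold[[fi]][[ci]]
          if (include_pka && fi == 1L) {
            mut_pka <- compute_pkas(assign_parameters(mons[[ci]], p), p,
                                    ph_grid = ph_grid)
            rep_pka <- pka_shift_report(wt_pkas[[ci]], mut_pka)
            sum_dpka[ci] <- rep_pka$sum_abs
          }
        }
        list(ok = TRUE, msg = "")
      }, error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
      if (!res$ok) { ok <- FALSE; note <- res$msg }
    }
    if (flip_sign) { ddg_f <- -ddg_f; ddd_b <- -ddd_b }
    row <- data.frame(site = site, wt_aa = AA1[[wt_aa]], aa = t1,
                      ddg_fold = mean(ddg_f), dddg_bind = mean(ddd_b),
                      sum_dpka = mean(sum_dpka),
                      ok = ok, note = note, stringsAsFactors = FALSE)
    for (fi in seq_along(ffnames)) {
      row[[paste0("ddg_fold_", ffnames[fi])]] <- mean(ddg_f[, fi])
      row[[paste0("dddg_bind_", ffnames[fi])]] <- mean(ddd_b[, fi])
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
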