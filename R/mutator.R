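# mutator: backbone-preserving side-chain replacement and single-site
# saturation mutagenesis. Mutant side chains are rebuilt from ideal internal
# geometry at candidate rotamers from a small backbone-independent library;
# the rotamer with the lowest clash score wins (first in library order on
# ties), which makes mutation fully deterministic.

#' Load a rotamer library
#'
#' Plain-text format: one rotamer per line, \code{AA chi1 chi2 chi3 chi4}
#' (unused chis \code{NA}). The bundled library holds 1-9 rotamers per
#' residue type at canonical chi values.
#'
#' @param path library file; default the bundled library.
#' @return a named list (by 3-letter code) of chi-angle matrices, class
#'   \code{RotamerLibrary}.
#' @export
load_rotamer_library <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "rotamers.txt", package = "satmut")
  }
  if (!file.exists(path)) stop("rotamer library not found: ", path)
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  tok <- strsplit(ln, "[[:space:]]+")
  lib <- list()
  for (t in tok) {
    aa <- t[1]
    chi <- suppressWarnings(as.numeric(t[-1]))
    lib[[aa]] <- rbind(lib[[aa]], chi)
  }
  for (aa in AA3) {
    nchi <- N_CHI[[aa]]
    if (nchi > 0 && (is.null(lib[[aa]]) || nrow(lib[[aa]]) < 1)) {
      stop("rotamer library lacks entries for ", aa)
    }
    if (!is.null(lib[[aa]])) rownames(lib[[aa]]) <- NULL
  }
  class(lib) <- "RotamerLibrary"
  lib
}

#' Steric clash score of one residue's side chain
#'
#' Sum over pairs (side-chain atom of the site, any atom at bond separation
#' >= 3 or in another residue/chain) of \code{max(0, r_overlap - d)^2} with
#' \code{r_overlap = 0.8 * (R_i + R_j)} (element radii). Zero means no
#' overlap.
#'
#' @param s a \code{Structure}.
#' @param chain_id,residue_number the site.
#' @return non-negative clash score (A^2 units).
#' @export
clash_score <- function(s, chain_id, residue_number) {
  ctx <- .clash_context(s, chain_id, residue_number)
  if (is.null(ctx)) return(0)
  .clash_eval(coords(s), ctx)
}

# Internal: precompute everything about the site that does not depend on the
# side-chain coordinates (excluded-partner sets from a depth-2 walk of the
# bond graph, element radii). NULL for glycine sites.
.clash_context <- function(s, chain_id, residue_number) {
  rows <- residue_rows(s, chain_id, residue_number)
  if (length(rows) == 0) stop("no residue ", residue_number, " in chain ",
                              chain_id)
  a <- s$atoms
  sc_rows <- rows[!(a$elety[rows] %in% BACKBONE_ATOMS)]
  if (length(sc_rows) == 0) return(NULL)
  n <- nrow(a)
  bl <- bond_list(s)
  # adjacency lists: the bond graph has O(n) edges, so a depth-2 walk from
  # each site atom is cheap; pairs closer than 3 bonds are never counted
  adj <- vector("list", n)
  for (k in seq_len(nrow(bl))) {
    i <- bl[k, 1]; j <- bl[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  rad <- ELEMENT_RADII[a$elesy]
  rad[is.na(rad)] <- 1.8
  partners <- lapply(sc_rows, function(i) {
    nb1 <- adj[[i]]
    excl <- unique(c(i, nb1, unlist(adj[nb1], use.names = FALSE)))
    p <- setdiff(seq_len(n), excl)
    # count each side-chain/side-chain pair of the site once
    p[!(p %in% sc_rows & p < i)]
  })
  list(sc_rows = sc_rows, partners = partners, rad = rad)
}

# Internal: evaluate the clash score on a coordinate matrix.
.clash_eval <- function(xyz, ctx) {
  score <- 0
  rad <- ctx$rad
  for (k in seq_along(ctx$sc_rows)) {
    i <- ctx$sc_rows[k]
    partners <- ctx$partners[[k]]
    if (length(partners) == 0) next
    d <- sqrt(colSums((t(xyz[partners, , drop = FALSE]) - xyz[i, ])^2))
    rov <- 0.8 * (rad[i] + rad[partners])
    score <- score + sum(pmax(0, rov - d)^2)
  }
  score
}

#' Mutation specification
#'
#' @param chain_id chain of the site.
#' @param residue_number residue number (file numbering).
#' @param target_aa target amino acid, 1- or 3-letter code.
#' @return a \code{MutationSpec}.
#' @export
mutation_spec <- function(chain_id, residue_number, target_aa) {
  target <- if (nchar(target_aa) == 1) aa123(target_aa) else toupper(target_aa)
  if (!target %in% AA3) stop("non-canonical target amino acid: ", target_aa)
  out <- list(chain_id = chain_id, residue_number = as.integer(residue_number),
              target_aa = target)
  class(out) <- "MutationSpec"
  out
}

#' @export
print.MutationSpec <- function(x, ...) {
  cat(sprintf("MutationSpec: %s%d -> %s\n", x$chain_id, x$residue_number,
              x$target_aa))
  invisible(x)
}

#' Mutate one residue in silico (backbone preserving)
#'
#' Replaces the side chain of the site with the target residue type rebuilt
#' from ideal internal geometry. Every rotamer of the library is scored with
#' \code{clash_score}; the lowest score wins (first in library order on
#' ties). Backbone atoms and all other residues never move. If every rotamer
#' clashes, the least-clashing one is still returned and the structure is
#' flagged (\code{attr(, "clash") = TRUE}); proline targets on non-proline
#' backbones are flagged \code{attr(, "pro_strain") = TRUE}.
#'
#' @param s a \code{Structure}.
#' @param spec a \code{MutationSpec}.
#' @param lib a \code{RotamerLibrary} (default: bundled).
#' @return mutated \code{Structure}.
#' @export
mutate_residue <- function(s, spec, lib = NULL) {
  stopifnot(inherits(s, "Structure"), inherits(spec, "MutationSpec"))
  if (is.null(lib)) lib <- load_rotamer_library()
  wt <- residue_aa(s, spec$chain_id, spec$residue_number)
  if (wt == spec$target_aa) stop("identity mutation: ", wt, " -> ",
                                 spec$target_aa)
  check_backbone(s, spec$chain_id, spec$residue_number)
  target <- spec$target_aa
  nchi <- N_CHI[[target]]
  if (nchi == 0) {
    out <- set_sidechain(s, spec$chain_id, spec$residue_number, target)
    attr(out, "clash") <- clash_score(out, spec$chain_id,
                                      spec$residue_number) > 0
    attr(out, "rotamer") <- NA_integer_
    return(out)
  }
  rots <- lib[[target]]
  if (is.null(rots)) stop("no rotamers for ", target)
  # build the mutant once; further rotamers only move its side-chain rows,
  # so the clash context (bond graph, exclusions) is computed a single time
  cand <- set_sidechain(s, spec$chain_id, spec$residue_number, target,
                        rots[1, seq_len(nchi)])
  ctx <- .clash_context(cand, spec$chain_id, spec$residue_number)
  rows <- residue_rows(cand, spec$chain_id, spec$residue_number)
  nm <- cand$atoms$elety[rows]
  bb <- list(
    N = as.numeric(cand$atoms[rows[match("N", nm)], c("x", "y", "z")]),
    CA = as.numeric(cand$atoms[rows[match("CA", nm)], c("x", "y", "z")]),
    C = as.numeric(cand$atoms[rows[match("C", nm)], c("x", "y", "z")]))
  sc_names <- cand$atoms$elety[ctx$sc_rows]
  xyz <- coords(cand)
  best_score <- Inf; best_k <- NA_integer_; best_chi <- NULL
  for (k in seq_len(nrow(rots))) {
    chi <- rots[k, seq_len(nchi)]
    sc <- build_sidechain(target, bb, chi)
    xyz[ctx$sc_rows, ] <- do.call(rbind, sc[sc_names])
    score <- .clash_eval(xyz, ctx)
    if (score < best_score - 1e-12) {  # strict improvement; first wins ties
      best_score <- score; best_k <- k; best_chi <- chi
    }
    if (best_score == 0) break
  }
  best <- if (best_k == 1L) cand else
    set_sidechain(s, spec$chain_id, spec$residue_number, target, best_chi)
  attr(best, "clash") <- best_score > 0
  attr(best, "clash_score") <- best_score
  attr(best, "rotamer") <- best_k
  if (target == "PRO" && wt != "PRO") attr(best, "pro_strain") <- TRUE
  best
}

#' Saturation scan of one site
#'
#' Builds the 19 single-site mutants (every canonical amino acid except the
#' wild type, alphabetical by one-letter code). All mutants share the wild
#' type's backbone coordinates.
#'
#' @param s a \code{Structure}.
#' @param chain_id,residue_number the site.
#' @param lib a \code{RotamerLibrary} (default: bundled).
#' @return list of 19 elements, each \code{list(spec, structure)}.
#' @export
saturation_scan <- function(s, chain_id, residue_number, lib = NULL) {
  if (is.null(lib)) lib <- load_rotamer_library()
  wt <- residue_aa(s, chain_id, residue_number)
  targets <- sort(setdiff(AA1, AA1[[wt]]))
  lapply(targets, function(t1) {
    spec <- mutation_spec(chain_id, residue_number, t1)
    list(spec = spec, structure = mutate_residue(s, spec, lib))
  })
}
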