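# structio: hierarchical structure container and PDB input/output.
#
# A Structure is a flat atom table (one row per heavy atom) plus metadata;
# the chain/residue hierarchy is implied by (chain, resno, insert) keys the
# way bio3d and most structural packages do it. File I/O is delegated to
# bio3d; this module adds the validation, altloc policy and numbering-offset
# bookkeeping the analysis needs.

ATOM_COLS <- c("chain", "resno", "insert", "resid", "elety", "elesy",
               "x", "y", "z", "het", "charge", "sigma", "epsilon", "gbr")

#' Create a Structure from an atom table
#'
#' @param atoms data.frame with columns chain, resno, insert, resid (3-letter
#'   residue code), elety (atom name), elesy (element), x, y, z and optionally
#'   het (logical, HETATM flag), charge, sigma, epsilon, gbr.
#' @param title free-text title.
#' @param numbering_offset integer added to file residue numbers when
#'   reporting (e.g. 2 for 3C6K-style inputs whose literature numbering is
#'   shifted).
#' @return an object of class \code{Structure}.
#' @export
new_structure <- function(atoms, title = "", numbering_offset = 0L) {
  stopifnot(is.data.frame(atoms))
  need <- c("chain", "resno", "resid", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss) > 0) stop("atom table lacks columns: ",
                             paste(miss, collapse = ", "))
  if (is.null(atoms$insert)) atoms$insert <- ""
  atoms$insert[is.na(atoms$insert)] <- ""
  if (is.null(atoms$het)) atoms$het <- FALSE
  for (col in c("charge", "sigma", "epsilon", "gbr")) {
    if (is.null(atoms[[col]])) atoms[[col]] <- NA_real_
  }
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z))) {
    stop("non-finite atom coordinates")
  }
  atoms <- atoms[, ATOM_COLS]
  rownames(atoms) <- NULL
  s <- list(atoms = atoms, title = title,
            numbering_offset = as.integer(numbering_offset))
  class(s) <- "Structure"
  validate_structure(s)
  s
}

validate_structure <- function(s) {
  a <- s$atoms
  # residue numbers strictly increasing within each protein chain
  for (ch in unique(a$chain[!a$het])) {
    rn <- unique(a$resno[a$chain == ch & !a$het])
    if (any(diff(rn) <= 0)) stop("residue numbers not strictly increasing in chain ", ch)
  }
  key <- paste(a$chain, a$resno, a$insert, a$elety, a$het)
  if (anyDuplicated(key)) {
    d <- a[duplicated(key), , drop = FALSE][1, ]
    stop(sprintf("duplicate atom %s in residue %s %s%d",
                 d$elety, d$resid, d$chain, d$resno))
  }
  invisible(s)
}

#' @export
print.Structure <- function(x, ...) {
  a <- x$atoms
  cat(sprintf("Structure: %d atoms, %d residues, chains [%s]%s\n",
              nrow(a), n_residues(x),
              paste(chain_ids(x), collapse = ","),
              if (nzchar(x$title)) paste0(" - ", x$title) else ""))
  invisible(x)
}

#' Basic Structure accessors
#'
#' @param s a \code{Structure}.
#' @return \code{chain_ids}: protein chain identifiers in file order;
#'   \code{n_residues}: number of protein residues; \code{coords}: n x 3
#'   coordinate matrix; \code{residue_table}: one row per protein residue.
#' @export
chain_ids <- function(s) unique(s$atoms$chain[!s$atoms$het])

#' @rdname chain_ids
#' @export
n_residues <- function(s) nrow(residue_table(s))

#' @rdname chain_ids
#' @export
coords <- function(s) as.matrix(s$atoms[, c("x", "y", "z")])

#' @rdname chain_ids
#' @export
residue_table <- function(s) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  key <- paste(a$chain, a$resno, a$insert)
  idx <- !duplicated(key)
  data.frame(chain = a$chain[idx], resno = a$resno[idx],
             insert = a$insert[idx], resid = a$resid[idx],
             stringsAsFactors = FALSE)
}

# Row indices of one residue's atoms.
residue_rows <- function(s, chain_id, resno, include_het = FALSE) {
  a <- s$atoms
  sel <- a$chain == chain_id & a$resno == resno
  if (!include_het) sel <- sel & !a$het
  which(sel)
}

# Amino-acid type of one residue (3-letter), error when absent.
residue_aa <- function(s, chain_id, resno) {
  rows <- residue_rows(s, chain_id, resno)
  if (length(rows) == 0) stop("no residue ", resno, " in chain ", chain_id)
  unique(s$atoms$resid[rows])[1]
}

check_backbone <- function(s, chain_id, resno) {
  rows <- residue_rows(s, chain_id, resno)
  have <- s$atoms$elety[rows]
  miss <- setdiff(BACKBONE_ATOMS, have)
  if (length(miss) > 0) {
    stop(sprintf("residue %s%d lacks backbone atoms: %s", chain_id, resno,
                 paste(miss, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Read a PDB file into a Structure
#'
#' Parses ATOM and HETATM records (via bio3d), retaining HETATM groups with a
#' non-protein flag. Alternate locations keep the highest-occupancy conformer
#' (first wins ties).
#'
#' @param path PDB file path.
#' @param numbering_offset reporting-numbering offset (2 for 3C6K-style files).
#' @return a \code{Structure}.
#' @export
read_pdb <- function(path, numbering_offset = 0L) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- tryCatch(suppressWarnings(bio3d::read.pdb(path, verbose = FALSE,
                                                   rm.alt = FALSE)),
                  error = function(e) stop("PDB format error in ", path, ": ",
                                           conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || sum(a$type == "ATOM") == 0) {
    stop("format error: no ATOM records in ", path)
  }
  # altloc policy: highest occupancy, first on tie
  a$alt[is.na(a$alt)] <- ""
  a$o[is.na(a$o)] <- 1
  if (any(nzchar(a$alt))) {
    key <- paste(a$chain, a$resno, a$insert, a$elety, a$type)
    ord <- order(match(key, unique(key)), -a$o)
    a <- a[ord, , drop = FALSE]
    a <- a[!duplicated(paste(a$chain, a$resno, a$insert, a$elety, a$type)), ,
           drop = FALSE]
    a <- a[order(as.integer(rownames(a))), , drop = FALSE]
  }
  a$insert[is.na(a$insert)] <- ""
  a$chain[is.na(a$chain)] <- " "
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy) | !nzchar(elesy))) {
    elesy <- substr(gsub("[^A-Za-z].*$", "", a$elety), 1, 1)
  }
  atoms <- data.frame(chain = a$chain, resno = a$resno, insert = a$insert,
                      resid = a$resid, elety = a$elety,
                      elesy = toupper(trimws(elesy)),
                      x = a$x, y = a$y, z = a$z,
                      het = a$type == "HETATM", stringsAsFactors = FALSE)
  new_structure(atoms, title = basename(path),
                numbering_offset = numbering_offset)
}

#' Write a Structure to a PDB file
#'
#' Standard fixed-column ATOM/HETATM records, occupancy 1.00, B-factor 0.00.
#'
#' @param s a \code{Structure} with at least one atom.
#' @param path output file path.
#' @export
write_pdb <- function(s, path) {
  stopifnot(inherits(s, "Structure"))
  a <- s$atoms
  if (nrow(a) == 0) stop("refusing to write an empty Structure")
  ok <- tryCatch({
    bio3d::write.pdb(file = path,
                     type = ifelse(a$het, "HETATM", "ATOM"),
                     xyz = as.vector(t(as.matrix(a[, c("x", "y", "z")]))),
                     resno = a$resno, resid = a$resid, eleno = seq_len(nrow(a)),
                     elety = a$elety, chain = a$chain,
                     insert = ifelse(nzchar(a$insert), a$insert, NA),
                     o = rep(1, nrow(a)), b = rep(0, nrow(a)),
                     elesy = a$elesy)
    TRUE
  }, error = function(e) stop("cannot write PDB to ", path, ": ",
                              conditionMessage(e)))
  invisible(path)
}

#' Truncate a chain to a residue range
#'
#' Keeps residues with start <= resno <= end (closed interval, file
#' numbering) of one chain; all other chains are dropped.
#'
#' @param s a \code{Structure}.
#' @param chain_id chain to truncate.
#' @param start,end first and last residue numbers kept.
#' @return a new \code{Structure} containing the selected domain.
#' @export
truncate_domain <- function(s, chain_id, start, end) {
  stopifnot(inherits(s, "Structure"))
  if (start > end) stop("precondition violated: start > end")
  if (!chain_id %in% s$atoms$chain) stop("no chain ", chain_id)
  keep <- s$atoms$chain == chain_id & s$atoms$resno >= start &
    s$atoms$resno <= end & !s$atoms$het
  if (!any(keep)) stop("no residues in range [", start, ",", end, "]")
  new_structure(s$atoms[keep, , drop = FALSE], title = s$title,
                numbering_offset = s$numbering_offset)
}

#' Extract a contiguous segment centred at a residue
#'
#' Used as the unfolded-state model: an odd-length window centred at the
#' mutation site, truncated (not padded) at chain termini. Coordinates are
#' copied unchanged.
#'
#' @param s a \code{Structure}.
#' @param chain_id chain of the site.
#' @param center residue number at the window centre.
#' @param length odd window length between 5 and 9 (default 7).
#' @return a single-chain \code{Structure} with the segment residues.
#' @export
extract_segment <- function(s, chain_id, center, length = 7L) {
  stopifnot(inherits(s, "Structure"))
  if (length %% 2L == 0L) stop("segment length must be odd")
  if (length < 5L || length > 9L) stop("segment length must be in [5, 9]")
  rt <- residue_table(s)
  rt <- rt[rt$chain == chain_id, , drop = FALSE]
  if (nrow(rt) == 0) stop("no chain ", chain_id)
  ci <- which(rt$resno == center)
  if (length(ci) == 0) stop("no residue ", center, " in chain ", chain_id)
  half <- (length - 1L) %/% 2L
  idx <- max(1L, ci - half):min(nrow(rt), ci + half)
  keep_resno <- rt$resno[idx]
  keep <- s$atoms$chain == chain_id & s$atoms$resno %in% keep_resno &
    !s$atoms$het
  new_structure(s$atoms[keep, , drop = FALSE], title = s$title,
                numbering_offset = s$numbering_offset)
}

#' Split a dimer into its two monomers (rigid-body protocol)
#'
#' Monomer coordinates are taken bit-identical from the dimer; no
#' re-relaxation happens. HETATM groups travel with their chain.
#'
#' @param dimer a two-chain \code{Structure}.
#' @return list of two single-chain \code{Structure}s, named by chain id.
#' @export
split_monomers <- function(dimer) {
  stopifnot(inherits(dimer, "Structure"))
  ids <- chain_ids(dimer)
  if (length(ids) != 2) stop("expected exactly 2 protein chains, found ",
                             length(ids))
  out <- lapply(ids, function(ch) {
    keep <- dimer$atoms$chain == ch
    new_structure(dimer$atoms[keep, , drop = FALSE], title = dimer$title,
                  numbering_offset = dimer$numbering_offset)
  })
  names(out) <- ids
  out
}

#' Report inter-chain steric clashes
#'
#' Lists inter-chain heavy-atom pairs closer than \code{scale} times the sum
#' of their element radii. Informational only; dimers are never auto-rejected.
#'
#' @param s a \code{Structure} with two or more chains.
#' @param scale overlap fraction defining a clash (default 0.6).
#' @return data.frame of clashing pairs with distances.
#' @export
clash_report <- function(s, scale = 0.6) {
  a <- s$atoms[!s$atoms$het, , drop = FALSE]
  xyz <- as.matrix(a[, c("x", "y", "z")])
  rad <- ELEMENT_RADII[a$elesy]
  rad[is.na(rad)] <- 1.8
  out <- list()
  ids <- unique(a$chain)
  for (i in seq_along(ids)) {
    for (j in seq_along(ids)) {
      if (j <= i) next
      ii <- which(a$chain == ids[i]); jj <- which(a$chain == ids[j])
      d <- sqrt(outer(rowSums(xyz[ii, , drop = FALSE]^2), rowSums(xyz[jj, , drop = FALSE]^2), `+`) -
                  2 * xyz[ii, , drop = FALSE] %*% t(xyz[jj, , drop = FALSE]))
      lim <- outer(rad[ii], rad[jj], `+`) * scale
      hit <- which(d < lim, arr.ind = TRUE)
      if (nrow(hit) > 0) {
        out[[length(out) + 1L]] <- data.frame(
          chain1 = ids[i], resno1 = a$resno[ii[hit[, 1]]],
          atom1 = a$elety[ii[hit[, 1]]],
          chain2 = ids[j], resno2 = a$resno[jj[hit[, 2]]],
          atom2 = a$elety[jj[hit[, 2]]],
          dist = d[hit], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(chain1 = character(0), resno1 = integer(0),
                      atom1 = character(0), chain2 = character(0),
                      resno2 = integer(0), atom2 = character(0),
                      dist = numeric(0)))
  }
  do.call(rbind, out)
}

#' Map file residue numbers to reporting numbers
#'
#' File numbering minus the offset gives reporting numbering: a 3C6K-style
#' file (offset 2) numbers the site G58 while the literature reports G56.
#'
#' @param s a \code{Structure}.
#' @param resno residue numbers in file numbering.
#' @return residue numbers in reporting (literature) numbering.
#' @export
reporting_number <- function(s, resno) resno - s$numbering_offset
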