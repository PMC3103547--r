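# Force-field parameter sets: named nonbonded parameter tables (partial
# charges per residue atom, LJ/GB parameters per atom class) read from
# plain-text files. Three sets (ff_a, ff_b, ff_c) are bundled; averaging the
# analysis over them emulates multi-force-field protocols without claiming
# equivalence to any published force field.

#' Read a force-field parameter set
#'
#' File format: whitespace-separated lines,
#' \code{CHARGE resid elety charge class} and
#' \code{CLASS class sigma epsilon gb_radius}; \code{#} comments allowed.
#'
#' @param path parameter file path.
#' @param name set name (defaults to the file name).
#' @param interior_dielectric,solvent_dielectric dielectric constants.
#' @return an object of class \code{ForceFieldParams}.
#' @export
read_forcefield <- function(path, name = NULL, interior_dielectric = 1.0,
                            solvent_dielectric = 78.5) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  ln <- readLines(path)
  ln <- trimws(sub("#.*$", "", ln))
  ln <- ln[nzchar(ln)]
  tok <- strsplit(ln, "[[:space:]]+")
  ch <- Filter(function(t) t[1] == "CHARGE", tok)
  cl <- Filter(function(t) t[1] == "CLASS", tok)
  if (length(ch) == 0 || length(cl) == 0) stop("malformed parameter file: ", path)
  charges <- data.frame(
    resid = vapply(ch, `[`, character(1), 2),
    elety = vapply(ch, `[`, character(1), 3),
    charge = as.numeric(vapply(ch, `[`, character(1), 4)),
    class = vapply(ch, `[`, character(1), 5),
    stringsAsFactors = FALSE)
  classes <- data.frame(
    class = vapply(cl, `[`, character(1), 2),
    sigma = as.numeric(vapply(cl, `[`, character(1), 3)),
    epsilon = as.numeric(vapply(cl, `[`, character(1), 4)),
    gb_radius = as.numeric(vapply(cl, `[`, character(1), 5)),
    stringsAsFactors = FALSE)
  if (any(classes$epsilon < 0)) stop("negative LJ epsilon in ", path)
  if (any(classes$sigma <= 0) || any(classes$gb_radius <= 0)) {
    stop("nonpositive LJ sigma or GB radius in ", path)
  }
  p <- list(name = if (is.null(name)) sub("\\.prm$", "", basename(path)) else name,
            charges = charges, classes = classes,
            interior_dielectric = interior_dielectric,
            solvent_dielectric = solvent_dielectric)
  class(p) <- "ForceFieldParams"
  p
}

#' Bundled parameter sets
#'
#' @param names which of the bundled sets to load.
#' @return list of \code{ForceFieldParams}.
#' @export
default_forcefields <- function(names = c("ff_a", "ff_b", "ff_c")) {
  lapply(names, function(nm) {
    path <- system.file("extdata", paste0(nm, ".prm"), package = "satmut")
    if (!nzchar(path)) stop("bundled parameter set not found: ", nm)
    read_forcefield(path, name = nm)
  })
}

#' @export
print.ForceFieldParams <- function(x, ...) {
  cat(sprintf("ForceFieldParams '%s': %d residue-atom charges, %d classes, eps_int=%g, eps_solv=%g\n",
              x$name, nrow(x$charges), nrow(x$classes),
              x$interior_dielectric, x$solvent_dielectric))
  invisible(x)
}

#' Assign nonbonded parameters to every atom of a Structure
#'
#' Fills the charge, sigma, epsilon and gbr atom columns from a parameter
#' set. Every protein atom must resolve; unparameterized atoms are an error
#' naming atom and residue.
#'
#' @param s a \code{Structure}.
#' @param p a \code{ForceFieldParams}.
#' @return the \code{Structure} with parameters filled in and the set name
#'   recorded in \code{s$param_set}.
#' @export
assign_parameters <- function(s, p) {
  stopifnot(inherits(s, "Structure"), inherits(p, "ForceFieldParams"))
  a <- s$atoms
  key <- paste(a$resid, a$elety)
  pkey <- paste(p$charges$resid, p$charges$elety)
  idx <- match(key, pkey)
  if (anyNA(idx)) {
    bad <- which(is.na(idx))[1]
    stop(sprintf("unparameterized atom %s in residue %s %s%d (set %s)",
                 a$elety[bad], a$resid[bad], a$chain[bad], a$resno[bad],
                 p$name))
  }
  cls <- p$charges$class[idx]
  cidx <- match(cls, p$classes$class)
  if (anyNA(cidx)) stop("unknown atom class: ", cls[which(is.na(cidx))[1]])
  a$charge <- p$charges$charge[idx]
  a$sigma <- p$classes$sigma[cidx]
  a$epsilon <- p$classes$epsilon[cidx]
  a$gbr <- p$classes$gb_radius[cidx]
  s$atoms <- a
  s$param_set <- p$name
  s
}

#' Total charge of a parameterized Structure
#'
#' @param s a parameterized \code{Structure}.
#' @return net charge in e.
#' @export
net_charge <- function(s) {
  if (anyNA(s$atoms$charge)) stop("structure not parameterized")
  sum(s$atoms$charge)
}
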