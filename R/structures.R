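#' Construct a Calpha structure model
#'
#' A `structure_model` is an ordered Calpha trace: author residue numbers,
#' one-letter amino-acid codes, coordinates in Angstrom and (for predicted
#' models) per-residue pLDDT confidence on the 0-100 scale.
#'
#' @param model_id identifier for the model.
#' @param resno integer vector of author residue numbers, strictly increasing.
#' @param aa character vector of one-letter residue codes.
#' @param xyz n x 3 numeric matrix of Calpha coordinates (Angstrom).
#' @param plddt numeric vector of per-residue confidence in \[0, 100\], or
#'   `NULL` when absent (experimental structures).
#' @return An object of class `structure_model`.
#' @export
structure_model <- function(model_id, resno, aa, xyz, plddt = NULL) {
  resno <- as.integer(resno)
  xyz <- as.matrix(xyz)
  n <- length(resno)
  if (n == 0) stop("empty model: no residues")
  if (length(aa) != n || nrow(xyz) != n || ncol(xyz) != 3)
    stop("resno, aa and xyz disagree in length")
  if (any(diff(resno) <= 0))
    stop("residue numbers must be strictly increasing")
  if (!is.null(plddt)) {
    if (length(plddt) != n) stop("plddt length mismatch")
    if (any(plddt < 0 | plddt > 100, na.rm = TRUE))
      stop("plddt values must lie in [0, 100]")
  }
  structure(list(model_id = as.character(model_id), resno = resno,
                 aa = as.character(aa), xyz = unname(xyz), plddt = plddt),
            class = "structure_model")
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("structure_model '%s': %d residues (%d-%d)%s\n",
              x$model_id, length(x$resno), min(x$resno), max(x$resno),
              if (is.null(x$plddt)) "" else
                sprintf(", mean pLDDT %.1f", mean(x$plddt))))
  invisible(x)
}

#' One-letter sequence of a model
#' @param model a [structure_model].
#' @return a single character string.
#' @export
model_sequence <- function(model) {
  paste(model$aa, collapse = "")
}

#' Read a Calpha trace from a PDB file
#'
#' Extracts one chain's Calpha atoms. For predicted models the B-factor
#' column holds per-residue pLDDT and is surfaced as such.
#'
#' @param file path to a PDB file.
#' @param chain chain identifier; `NULL` takes the first chain present.
#' @param is_model logical; if `TRUE` the B-factor column is interpreted as
#'   pLDDT confidence.
#' @param model_id identifier; defaults to the file name without extension.
#' @return A [structure_model].
#' @export
read_structure <- function(file, chain = NULL, is_model = TRUE,
                           model_id = NULL) {
  if (is.null(model_id))
    model_id <- sub("\\.[^.]*$", "", basename(file))
  pdb <- bio3d::read.pdb(file, verbose = FALSE)
  atoms <- pdb$atom
  if (is.null(chain)) chain <- atoms$chain[1]
  in_chain <- atoms$chain == chain & !is.na(atoms$chain)
  if (!any(in_chain))
    stop(sprintf("chain '%s' not found in %s (chains: %s)", chain, file,
                 paste(unique(atoms$chain), collapse = ", ")))
  ca <- atoms[in_chain & atoms$elety == "CA" & atoms$type == "ATOM", ,
              drop = FALSE]
  if (nrow(ca) == 0)
    stop(sprintf("chain '%s' of %s has no Calpha atoms", chain, file))
  ## keep the first altloc of each residue
  ca <- ca[!duplicated(ca$resno), , drop = FALSE]
  skipped <- setdiff(unique(atoms$resno[in_chain & atoms$type == "ATOM"]),
                     ca$resno)
  if (length(skipped) > 0)
    warning(sprintf("%d residue(s) without Calpha skipped in %s chain %s",
                    length(skipped), basename(file), chain))
  structure_model(
    model_id = model_id,
    resno = ca$resno,
    aa = bio3d::aa321(ca$resid),
    xyz = cbind(ca$x, ca$y, ca$z),
    plddt = if (is_model) ca$b else NULL)
}

#' Write a Calpha trace as a PDB file
#'
#' pLDDT values, when present, are written to the B-factor column.
#'
#' @param model a [structure_model].
#' @param file output path.
#' @param chain chain identifier to write.
#' @export
write_structure <- function(model, file, chain = "A") {
  stopifnot(inherits(model, "structure_model"))
  n <- length(model$resno)
  b <- if (is.null(model$plddt)) rep(0, n) else model$plddt
  bio3d::write.pdb(file = file,
                   xyz = as.vector(t(model$xyz)),
                   resno = model$resno,
                   resid = bio3d::aa123(model$aa),
                   eleno = seq_len(n),
                   elety = rep("CA", n),
                   chain = rep(chain, n),
                   o = rep(1, n), b = b)
  invisible(file)
}

#' Remove residue ranges from a model
#'
#' Drops all residues whose author numbers fall inside any of the given
#' inclusive intervals, e.g. terminal truncations such as 1-131 and 401-461.
#'
#' @param model a [structure_model].
#' @param drop_ranges list of length-2 integer vectors `c(lo, hi)`, inclusive.
#' @return The truncated [structure_model].
#' @export
truncate_model <- function(model, drop_ranges) {
  stopifnot(inherits(model, "structure_model"))
  if (length(drop_ranges) == 0) return(model)
  if (is.numeric(drop_ranges)) drop_ranges <- list(drop_ranges)
  drop <- rep(FALSE, length(model$resno))
  for (rg in drop_ranges) {
    if (length(rg) != 2 || rg[1] > rg[2])
      stop(sprintf("invalid interval [%s]", paste(rg, collapse = ", ")))
    drop <- drop | (model$resno >= rg[1] & model$resno <= rg[2])
  }
  if (all(drop)) stop("truncation removes every residue")
  structure_model(model$model_id, model$resno[!drop], model$aa[!drop],
                  model$xyz[!drop, , drop = FALSE],
                  if (is.null(model$plddt)) NULL else model$plddt[!drop])
}

#' Residue correspondence between two models
#'
#' Establishes an order-preserving residue map by global sequence alignment
#' of the two amino-acid sequences, restricted to positions where both
#' structures have a resolved Calpha. Needed because experimental structures
#' carry unresolved residues and references may be near-identical homologs.
#'
#' @param a,b [structure_model]s.
#' @param ... passed to the aligner (substitution matrix, gap penalties).
#' @return A `residue_map`: data frame with positional indices `ia`, `ib`
#'   into `a` and `b`, plus attribute `coverage` (fraction of `a`'s residues
#'   mapped).
#' @export
correspond <- function(a, b, ...) {
  stopifnot(inherits(a, "structure_model"), inherits(b, "structure_model"))
  al <- align_global(model_sequence(a), model_sequence(b), ...)
  ca <- strsplit(al$a, "")[[1]]
  cb <- strsplit(al$b, "")[[1]]
  ia <- cumsum(ca != "-")
  ib <- cumsum(cb != "-")
  keep <- ca != "-" & cb != "-"
  map <- data.frame(ia = ia[keep], ib = ib[keep])
  if (nrow(map) == 0) stop("no residue overlap between models")
  attr(map, "coverage") <- nrow(map) / length(a$resno)
  class(map) <- c("residue_map", class(map))
  map
}

#' Identity residue map over shared residue numbers
#'
#' Matches residues of two models by author residue number. Suitable for
#' same-sequence ensembles where alignment is unnecessary.
#'
#' @param a,b [structure_model]s.
#' @return A `residue_map` as in [correspond()].
#' @export
match_by_resno <- function(a, b) {
  shared <- intersect(a$resno, b$resno)
  if (length(shared) == 0) stop("no residue overlap between models")
  map <- data.frame(ia = match(shared, a$resno), ib = match(shared, b$resno))
  attr(map, "coverage") <- nrow(map) / length(a$resno)
  class(map) <- c("residue_map", class(map))
  map
}
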