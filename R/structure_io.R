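## Residue-level structure input: PDB/mmCIF parsing (via bio3d), reduction
## to one effective atom per residue, and selection resolution.

# non-standard residues with an accepted parent amino acid
NONSTANDARD_MAP <- c(
  MSE = "MET", SEC = "CYS", MLY = "LYS", CSO = "CYS", HYP = "PRO",
  PTR = "TYR", SEP = "SER", TPO = "THR", PCA = "GLU"
)

STANDARD_AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

#' Read a protein structure
#'
#' Parses a PDB or mmCIF file (dispatching on the file extension) and
#' returns its heavy-atom protein residues for one model.  Waters,
#' detergents, ligands and other hetero groups are excluded; non-standard
#' residues with a conventional parent amino acid (e.g. selenomethionine
#' MSE) are mapped to the parent.  Hydrogens are dropped even when present.
#' Alternate locations are resolved to the highest-occupancy conformer
#' (ties broken by altloc letter order).
#'
#' @param path path to a `.pdb` / `.ent` or `.cif` file.
#' @param model 1-based model number for multi-model (NMR) entries;
#'   default 1.
#' @param lenient if `TRUE`, unmappable non-standard residues are kept and
#'   flagged `UNK` instead of raising an error.
#' @return a data frame of atoms with class `"fod_atoms"`: columns `chain`,
#'   `resno`, `insert`, `resid` (3-letter), `aa` (1-letter, `X` for UNK),
#'   `elety`, `x`, `y`, `z`.
#' @seealso [effective_atoms()] to reduce to one point per residue.
#' @export
read_structure <- function(path, model = 1, lenient = FALSE) {
  if (!file.exists(path))
    fodm_stop(sprintf("structure file not found: %s", path),
              "fodm_parse_error")
  is_cif <- grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE)
  pdb <- tryCatch(
    if (is_cif) bio3d::read.cif(path, multi = TRUE, verbose = FALSE,
                                rm.alt = FALSE)
    else suppressWarnings(bio3d::read.pdb(path, multi = TRUE,
                                          verbose = FALSE, rm.alt = FALSE)),
    error = function(e)
      fodm_stop(sprintf("cannot parse %s: %s", path, conditionMessage(e)),
                "fodm_parse_error"))

  n_models <- max(1L, nrow(pdb$xyz))
  if (model < 1 || model > n_models)
    fodm_stop(sprintf("model %d out of range (file has %d model%s)",
                      model, n_models, if (n_models == 1) "" else "s"),
              "fodm_range_error")

  at <- pdb$atom
  # coordinates of the requested model
  xyz <- matrix(pdb$xyz[model, ], ncol = 3, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  # protein residues only: standard ATOM records plus mappable HETATMs
  mapped <- at$resid %in% names(NONSTANDARD_MAP)
  keep <- (at$type == "ATOM" & at$resid %in% STANDARD_AA3) | mapped
  if (lenient) keep <- keep | (at$type == "ATOM")
  at <- at[keep, , drop = FALSE]
  if (nrow(at) == 0)
    fodm_stop("no protein residues found", "fodm_parse_error")
  at$resid[at$resid %in% names(NONSTANDARD_MAP)] <-
    NONSTANDARD_MAP[at$resid[at$resid %in% names(NONSTANDARD_MAP)]]

  # drop hydrogens/deuterium by element symbol (fall back to atom name)
  elesy <- at$elesy
  if (is.null(elesy) || all(is.na(elesy)))
    elesy <- sub("^[0-9]*([A-Za-z]).*$", "\\1", at$elety)
  at <- at[!(toupper(trimws(elesy)) %in% c("H", "D")), , drop = FALSE]

  # alternate locations: highest occupancy, ties by altloc letter
  alt <- at$alt
  if (!is.null(alt) && any(!is.na(alt) & alt != "")) {
    occ <- at$o
    occ[is.na(occ)] <- 1
    key <- paste(at$chain, at$resno, at$insert, at$elety, sep = "\r")
    ord <- order(key, -occ, ifelse(is.na(alt) | alt == "", "", alt))
    at2 <- at[ord, , drop = FALSE]
    at <- at2[!duplicated(paste(at2$chain, at2$resno, at2$insert,
                                at2$elety, sep = "\r")), , drop = FALSE]
    at <- at[order(match(rownames(at), rownames(pdb$atom))), , drop = FALSE]
  }

  aa <- suppressWarnings(bio3d::aa321(at$resid))
  aa[is.na(aa) | !aa %in% strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]] <- "X"
  if (any(aa == "X") && !lenient)
    fodm_stop(sprintf(
      "unmappable residue type(s): %s (use lenient = TRUE to keep as UNK)",
      paste(unique(at$resid[aa == "X"]), collapse = ", ")),
      "fodm_parse_error")

  out <- data.frame(chain = at$chain, resno = at$resno,
                    insert = ifelse(is.na(at$insert), "", at$insert),
                    resid = at$resid, aa = aa, elety = at$elety,
                    x = at$x, y = at$y, z = at$z,
                    stringsAsFactors = FALSE)
  attr(out, "source") <- path
  attr(out, "model") <- model
  class(out) <- c("fod_atoms", "data.frame")
  out
}

#' Reduce residues to effective atoms
#'
#' Each residue is represented by a single effective atom: the unweighted
#' arithmetic mean of its heavy-atom coordinates.  Residue order is
#' preserved.
#'
#' @param atoms a `"fod_atoms"` data frame from [read_structure()], or any
#'   data frame with columns `chain`, `resno`, `x`, `y`, `z` (optionally
#'   `insert`, `aa`).
#' @param label optional label stored on the result.
#' @return a data frame of class `"eff_structure"` with one row per residue:
#'   `chain`, `resno`, `insert`, `aa`, `x`, `y`, `z`, `n_atoms`.
#' @examples
#' at <- data.frame(chain = "A", resno = 1, aa = "A",
#'                  x = c(0, 2), y = 0, z = 0)
#' effective_atoms(at)   # effective point (1, 0, 0)
#' @export
effective_atoms <- function(atoms, label = NULL) {
  if (is.null(atoms) || nrow(atoms) == 0)
    fodm_stop("empty residue list", "fodm_value_error")
  if (is.null(atoms$insert)) atoms$insert <- ""
  if (is.null(atoms$aa)) atoms$aa <- "X"
  key <- paste(atoms$chain, atoms$resno, atoms$insert, sep = "\r")
  idx <- split(seq_len(nrow(atoms)), factor(key, levels = unique(key)))
  first <- vapply(idx, `[`, integer(1), 1L)
  out <- data.frame(
    chain  = atoms$chain[first],
    resno  = atoms$resno[first],
    insert = atoms$insert[first],
    aa     = atoms$aa[first],
    x = vapply(idx, function(i) mean(atoms$x[i]), numeric(1)),
    y = vapply(idx, function(i) mean(atoms$y[i]), numeric(1)),
    z = vapply(idx, function(i) mean(atoms$z[i]), numeric(1)),
    n_atoms = lengths(idx),
    row.names = NULL, stringsAsFactors = FALSE)
  if (!is.null(atoms$h)) out$h <- atoms$h[first]
  attr(out, "label") <- label %||% attr(atoms, "source")
  class(out) <- c("eff_structure", "data.frame")
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

eff_points <- function(es) cbind(es$x, es$y, es$z)

as_eff_structure <- function(x) {
  if (inherits(x, "eff_structure")) return(x)
  if (inherits(x, "fod_atoms")) return(effective_atoms(x))
  fodm_stop("expected an eff_structure or fod_atoms object",
            "fodm_value_error")
}

#' Declare a residue selection
#'
#' Selections name the analysis units of the model's four granularities:
#' a whole `complex`, a `domain_set` (corresponding fragments across all
#' chains of a complex, the DD# units), a single `chain`, an
#' `individual_domain` (D#), or a `fragment_in_complex`, which is scored by
#' slicing the parent complex's profiles rather than refitting.
#'
#' @param name label used in reports (e.g. `"DD1"`).
#' @param units selection string such as `"A:18-116,B:18-116"` (chain, or
#'   chain:from-to; ranges inclusive, author numbering), or a data frame
#'   with columns `chain`, `start`, `end` (NA start/end = whole chain).
#' @param mode one of `"complex"`, `"domain_set"`, `"chain"`,
#'   `"individual_domain"`, `"fragment_in_complex"`.
#' @param parent for `fragment_in_complex`, the `name` of the parent
#'   selection whose profiles are sliced.
#' @return an object of class `"fod_selection"`.
#' @examples
#' selection("DD1", "A:18-116,B:18-116", mode = "domain_set")
#' @export
selection <- function(name, units,
                      mode = c("complex", "domain_set", "chain",
                               "individual_domain", "fragment_in_complex"),
                      parent = NULL) {
  mode <- match.arg(mode)
  if (is.character(units)) units <- parse_selection(units)
  stopifnot(is.data.frame(units),
            all(c("chain", "start", "end") %in% names(units)))
  if (mode == "fragment_in_complex" && is.null(parent))
    fodm_stop("fragment_in_complex selections need a parent selection name",
              "fodm_selection_error")
  # ranges within a chain must not overlap
  for (ch in unique(units$chain)) {
    u <- units[units$chain == ch & !is.na(units$start), , drop = FALSE]
    if (nrow(u) > 1) {
      u <- u[order(u$start), ]
      if (any(u$start[-1] <= u$end[-nrow(u)]))
        fodm_stop(sprintf("overlapping ranges in chain %s of selection '%s'",
                          ch, name), "fodm_selection_error")
    }
  }
  structure(list(name = name, units = units, mode = mode, parent = parent),
            class = "fod_selection")
}

#' Parse a selection string
#'
#' Syntax: comma-separated units, each `CHAIN` (whole chain) or
#' `CHAIN:FROM-TO` (inclusive author-numbered range), e.g.
#' `"A:18-116,B:18-116"` or `"A,B"`.
#'
#' @param text selection string.
#' @return data frame with columns `chain`, `start`, `end` (`NA` for whole
#'   chain).
#' @export
parse_selection <- function(text) {
  parts <- trimws(strsplit(text, ",", fixed = TRUE)[[1]])
  parts <- parts[nzchar(parts)]
  if (length(parts) == 0)
    fodm_stop("empty selection string", "fodm_parse_error")
  rows <- lapply(parts, function(p) {
    if (grepl(":", p, fixed = TRUE)) {
      m <- regmatches(p, regexec("^([^:]+):(-?[0-9]+)-(-?[0-9]+)$", p))[[1]]
      if (length(m) != 4)
        fodm_stop(sprintf("cannot parse selection unit '%s'", p),
                  "fodm_parse_error")
      data.frame(chain = m[2], start = as.integer(m[3]),
                 end = as.integer(m[4]), stringsAsFactors = FALSE)
    } else {
      data.frame(chain = p, start = NA_integer_, end = NA_integer_,
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  bad <- !is.na(out$start) & out$start > out$end
  if (any(bad))
    fodm_stop("selection range with start > end", "fodm_parse_error")
  out
}

#' Resolve a selection against a structure
#'
#' Returns the sub-structure containing exactly the selected residues, in
#' the order the selection's units are listed (within a unit, file order,
#' i.e. sequence order).
#'
#' @param structure an `"eff_structure"` (or `"fod_atoms"`, reduced first).
#' @param sel a [selection()] (or selection string, taken as mode `chain`
#'   set semantics).
#' @param lenient if `TRUE`, residues declared in a range but absent from
#'   the structure are dropped with a warning instead of raising an error.
#' @return an `"eff_structure"` restricted to the selection.
#' @export
resolve_selection <- function(structure, sel, lenient = FALSE) {
  es <- as_eff_structure(structure)
  if (is.character(sel)) sel <- selection(sel, sel, mode = "chain")
  units <- sel$units
  pick <- integer(0)
  for (i in seq_len(nrow(units))) {
    ch <- units$chain[i]
    in_chain <- which(es$chain == ch)
    if (length(in_chain) == 0)
      fodm_stop(sprintf("selection '%s': chain %s not present in structure",
                        sel$name, ch), "fodm_selection_error")
    if (is.na(units$start[i])) {
      pick <- c(pick, in_chain)
    } else {
      rows <- in_chain[es$resno[in_chain] >= units$start[i] &
                       es$resno[in_chain] <= units$end[i]]
      declared <- units$start[i]:units$end[i]
      missing <- setdiff(declared, es$resno[rows])
      if (length(missing) > 0) {
        msg <- sprintf(
          "selection '%s': chain %s is missing residue(s) %s",
          sel$name, ch, paste(utils::head(missing, 8), collapse = ", "))
        if (lenient) fodm_warn(paste0(msg, " (lenient: kept what exists)"))
        else fodm_stop(msg, "fodm_selection_error")
      }
      pick <- c(pick, rows)
    }
  }
  out <- es[pick, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "label") <- sel$name
  class(out) <- c("eff_structure", "data.frame")
  out
}
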