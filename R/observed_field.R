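## Observed hydrophobicity: distance-damped pairwise interactions between
## residues, each weighted by intrinsic hydrophobicity.

# Kyte-Doolittle hydropathy rescaled to [0,1] (min -4.5 -> 0, max 4.5 -> 1)
KD_RAW <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5, Q = -3.5,
            E = -3.5, G = -0.4, H = -3.2, I =  4.5, L =  3.8, K = -3.9,
            M =  1.9, F =  2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
            Y = -1.3, V =  4.2)

#' Intrinsic hydrophobicity scales
#'
#' Any per-residue scale can drive the observed distribution; the shipped
#' default is the Kyte-Doolittle hydropathy index rescaled linearly to
#' \[0, 1\].  Because RD and K values depend on the scale, the scale name is
#' recorded in every output's convention block.
#'
#' @param name scale name; currently `"kd_norm"` (Kyte-Doolittle, rescaled).
#' @return named numeric vector over the 20 one-letter amino-acid codes,
#'   values in \[0, 1\], with attribute `name`.
#' @export
hydrophobicity_scale <- function(name = "kd_norm") {
  if (name != "kd_norm")
    fodm_stop(sprintf("unknown hydrophobicity scale '%s'", name),
              "fodm_value_error")
  h <- (KD_RAW - min(KD_RAW)) / (max(KD_RAW) - min(KD_RAW))
  attr(h, "name") <- name
  h
}

#' Load a hydrophobicity scale from a file
#'
#' Expects two whitespace-separated columns: one-letter amino-acid code and
#' value.  Values are rescaled to \[0, 1\] unless already within it.
#'
#' @param path text file path.
#' @param name label recorded on the scale (default the file name).
#' @return named numeric vector as in [hydrophobicity_scale()].
#' @export
read_scale <- function(path, name = basename(path)) {
  tb <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  if (ncol(tb) < 2)
    fodm_stop("scale file must have two columns: code, value",
              "fodm_parse_error")
  h <- setNames(as.numeric(tb[[2]]), toupper(tb[[1]]))
  need <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  if (!all(need %in% names(h)))
    fodm_stop(sprintf("scale is missing amino acid(s): %s",
                      paste(setdiff(need, names(h)), collapse = ", ")),
              "fodm_parse_error")
  h <- h[need]
  if (min(h) < 0 || max(h) > 1) h <- (h - min(h)) / (max(h) - min(h))
  attr(h, "name") <- name
  h
}

#' Distance-damping interaction kernel
#'
#' Polynomial contact function of Levitt form: 1 at zero separation,
#' falling smoothly to 0 at the cutoff `c` and zero beyond it:
#' for `r < c`, `1 - (7(r/c)^2 - 9(r/c)^4 + 5(r/c)^6 - (r/c)^8) / 2`.
#'
#' @param r inter-residue distance(s), Angstrom (>= 0).
#' @param c cutoff, Angstrom (> 0); default 9.
#' @return kernel value(s) in \[0, 1\].
#' @examples
#' kernel_value(c(0, 4.5, 9), c = 9)
#' @export
kernel_value <- function(r, c = 9) {
  if (length(c) != 1L || !is.finite(c) || c <= 0)
    fodm_stop("cutoff c must be a single positive number",
              "fodm_value_error")
  if (any(r < 0)) fodm_stop("distances must be >= 0", "fodm_value_error")
  u2 <- (r / c)^2
  k <- 1 - 0.5 * (7 * u2 - 9 * u2^2 + 5 * u2^3 - u2^4)
  k[r >= c] <- 0
  pmin(pmax(k, 0), 1)
}

residue_h <- function(es, scale, lenient = FALSE) {
  if (!is.null(es$h)) return(as.numeric(es$h))
  h <- unname(scale[es$aa])
  if (anyNA(h)) {
    bad <- unique(es$aa[is.na(h)])
    if (!lenient)
      fodm_stop(sprintf("no hydrophobicity value for residue type(s): %s",
                        paste(bad, collapse = ", ")), "fodm_scale_error")
    fodm_warn(sprintf("residue type(s) %s assigned mid-scale hydrophobicity",
                      paste(bad, collapse = ", ")))
    h[is.na(h)] <- 0.5
  }
  h
}

#' Observed hydrophobicity profile O
#'
#' Each residue collects hydrophobic interactions from all others within the
#' kernel cutoff: `Oi_raw = sum_{j != i} pair(H_i, H_j) * kernel(r_ij, c)`
#' with the pair term `H_i + H_j` by default, then normalised to sum 1.
#' Residues carrying an explicit `h` column (synthetic structures) use it
#' directly; otherwise intrinsic hydrophobicity comes from `scale`.
#'
#' @param structure an `"eff_structure"`.
#' @param scale hydrophobicity scale ([hydrophobicity_scale()] by default).
#' @param cutoff kernel cutoff in Angstrom (default 9).
#' @param pair pair term: `"sum"` (`H_i + H_j`, default), `"product"`, or
#'   `"partner"` (`H_j` only).
#' @param lenient pass-through for unknown residue types (see
#'   [residue hydrophobicity][hydrophobicity_scale()]).
#' @return an O-role [fod_profile].  If no residue pair falls within the
#'   cutoff the raw sums are all zero and a uniform profile is returned
#'   with a warning.
#' @export
o_profile <- function(structure, scale = hydrophobicity_scale(),
                      cutoff = 9, pair = c("sum", "product", "partner"),
                      lenient = FALSE) {
  pair <- match.arg(pair)
  es <- as_eff_structure(structure)
  h <- residue_h(es, scale, lenient)
  n <- nrow(es)
  if (n == 1L)
    return(fod_profile(1, role = "O", selection = attr(es, "label"),
                       normalize = FALSE))
  K <- kernel_value(as.matrix(dist(eff_points(es))), c = cutoff)
  diag(K) <- 0                           # self term excluded
  raw <- switch(pair,
    sum     = h * rowSums(K) + as.numeric(K %*% h),
    product = h * as.numeric(K %*% h),
    partner = as.numeric(K %*% h))
  if (sum(raw) <= 0) {
    fodm_warn("no residue pairs within the cutoff; O falls back to uniform")
    raw <- rep(1, n)
  }
  fod_profile(raw, role = "O", selection = attr(es, "label"))
}
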