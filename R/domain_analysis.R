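## Orchestration of the analysis grid: whole complexes, domain sets (DD#),
## single chains, individual domains (D#), and fragments scored inside
## their parent complex.

conventions_record <- function(scale, cutoff, pair, sigma_margin,
                               k_max, step) {
  list(scale = attr(scale, "name") %||% "custom",
       kernel = "levitt-poly", kernel_cutoff = cutoff, pair_term = pair,
       sigma_rule = "extent/3", sigma_margin = sigma_margin,
       k_max = k_max, k_step = step)
}

#' Score a set of selections against one structure
#'
#' Runs the full pipeline for each selection of an analysis plan.  For the
#' modes `complex`, `domain_set`, `chain` and `individual_domain`, a fresh
#' Gaussian field is fitted to the selected residues and O is computed from
#' interactions within the selection.  For `fragment_in_complex`, the T and
#' O profiles are computed once on the parent selection, the fragment's
#' rows are sliced out and renormalised, and R is rebuilt as `1/n_fragment`
#' — the fragment is scored in the force field of (and interacting with)
#' the whole parent.
#'
#' @param structure an `"eff_structure"` (or `"fod_atoms"`).
#' @param selections a list of [selection()] objects (or a single one).
#' @param scale,cutoff,pair observed-field settings, see [o_profile()].
#' @param sigma_margin,sigma_floor Gaussian-field settings, see
#'   [fit_gaussian()].
#' @param k_max,step K-search settings, see [optimize_k()].
#' @param r_equiv also report the R-equivalence K per selection.
#' @param lenient tolerate missing residues in declared ranges.
#' @return object of class `"fod_analysis"`: list with `scores` (one row
#'   per selection: `name`, `mode`, `n`, `rd`, `k`, `k_opt`, `dkl_ot`,
#'   `dkl_or`, `dkl_om_min`, `k_r_equiv`), `profiles` (named list of
#'   per-selection T/O/R/M profiles and residue ids), and `conventions`.
#' @export
analyze <- function(structure, selections,
                    scale = hydrophobicity_scale(), cutoff = 9,
                    pair = "sum", sigma_margin = 0, sigma_floor = 1.0,
                    k_max = 10, step = 0.01, r_equiv = FALSE,
                    lenient = FALSE) {
  es <- as_eff_structure(structure)
  if (inherits(selections, "fod_selection")) selections <- list(selections)
  names(selections) <- vapply(selections, `[[`, character(1), "name")
  conv <- conventions_record(scale, cutoff, pair, sigma_margin, k_max, step)

  # cache of parent (T, O, substructure) for fragment_in_complex slicing
  parent_cache <- new.env(parent = emptyenv())
  whole_profiles <- function(sel_name) {
    if (!is.null(parent_cache[[sel_name]])) return(parent_cache[[sel_name]])
    if (!sel_name %in% names(selections))
      fodm_stop(sprintf("parent selection '%s' is not in the plan",
                        sel_name), "fodm_selection_error")
    sub <- resolve_selection(es, selections[[sel_name]], lenient = lenient)
    field <- fit_gaussian(sub, sigma_margin = sigma_margin,
                          sigma_floor = sigma_floor)
    out <- list(sub = sub,
                t = t_profile(sub, field),
                o = o_profile(sub, scale, cutoff = cutoff, pair = pair,
                              lenient = lenient))
    parent_cache[[sel_name]] <- out
    out
  }

  rows <- list(); profiles <- list()
  for (sel in selections) {
    res <- tryCatch(
      {
        if (sel$mode == "fragment_in_complex") {
          par <- whole_profiles(sel$parent)
          frag <- resolve_selection(es, sel, lenient = lenient)
          idx <- match(paste(frag$chain, frag$resno, frag$insert),
                       paste(par$sub$chain, par$sub$resno, par$sub$insert))
          if (anyNA(idx))
            fodm_stop(sprintf(
              "selection '%s' is not contained in parent '%s'",
              sel$name, sel$parent), "fodm_selection_error")
          list(sub = frag,
               t = fod_profile(as.numeric(par$t)[idx], "T", sel$name),
               o = fod_profile(as.numeric(par$o)[idx], "O", sel$name))
        } else {
          sub <- resolve_selection(es, sel, lenient = lenient)
          field <- fit_gaussian(sub, sigma_margin = sigma_margin,
                                sigma_floor = sigma_floor)
          list(sub = sub, t = t_profile(sub, field),
               o = o_profile(sub, scale, cutoff = cutoff, pair = pair,
                             lenient = lenient))
        }
      },
      error = function(e) {
        if (inherits(e, "fodm_error")) stop(e)
        fodm_stop(sprintf("selection '%s': %s", sel$name,
                          conditionMessage(e)), "fodm_numeric_error")
      })
    sc <- fod_score(res$o, res$t, selection_name = sel$name,
                    conventions = conv, k_max = k_max, step = step,
                    r_equiv = r_equiv)
    m <- m_profile(res$t, sc$k_opt)
    rows[[sel$name]] <- data.frame(
      name = sel$name, mode = sel$mode, n = sc$n, rd = sc$rd,
      k = sc$k, k_opt = sc$k_opt, dkl_ot = sc$dkl_ot, dkl_or = sc$dkl_or,
      dkl_om_min = sc$dkl_om_min, k_r_equiv = sc$k_r_equiv,
      stringsAsFactors = FALSE)
    profiles[[sel$name]] <- list(
      residues = res$sub[, c("chain", "resno", "insert", "aa")],
      t = res$t, o = res$o, r = r_profile(sc$n), m = m)
  }
  scores <- do.call(rbind, rows)
  rownames(scores) <- NULL
  structure(list(scores = scores, profiles = profiles, conventions = conv,
                 label = attr(es, "label")),
            class = "fod_analysis")
}

#' @export
print.fod_analysis <- function(x, ...) {
  cat(sprintf("<fod_analysis> %s: %d selection(s)\n",
              x$label %||% "(unlabelled structure)", nrow(x$scores)))
  df <- x$scores
  df$rd <- round(df$rd, 3)
  print(df[, c("name", "mode", "n", "rd", "k")], row.names = FALSE)
  invisible(x)
}

#' Hydrophobic-core residues
#'
#' Residues where both the theoretical and the observed hydrophobicity
#' exceed a threshold (0.01 by convention) form the hydrophobic core of a
#' micelle-like structure.
#'
#' @param t,o profiles of equal length.
#' @param threshold inclusion threshold applied to both profiles.
#' @return list with `indices` (1-based positions satisfying both
#'   conditions) and `threshold`.
#' @examples
#' core_residues(c(0.02, 0.005, 0.02), c(0.02, 0.02, 0.005))  # index 1
#' @export
core_residues <- function(t, o, threshold = 0.01) {
  t <- as.numeric(t); o <- as.numeric(o)
  if (length(t) != length(o))
    fodm_stop("T and O must have equal length", "fodm_shape_error")
  list(indices = which(t > threshold & o > threshold),
       threshold = threshold)
}

#' Read an analysis plan file
#'
#' Plans are small YAML files declaring the structure and the selection
#' grid, e.g.:
#' ```yaml
#' structure: 4hw9.pdb
#' selections:
#'   - {name: Complex, mode: complex, units: "A,B,C,D,E,F,G"}
#'   - {name: DD1, mode: domain_set, units: "A:18-116,B:18-116"}
#'   - {name: "frag 18-116", mode: fragment_in_complex,
#'      units: "A:18-116", parent: Complex}
#' ```
#'
#' @param path YAML plan file.
#' @return list with `structure` (path, resolved relative to the plan file
#'   unless absolute), `model`, and `selections` (list of [selection()]).
#' @export
read_plan <- function(path) {
  if (!file.exists(path))
    fodm_stop(sprintf("plan file not found: %s", path), "fodm_parse_error")
  y <- yaml::read_yaml(path)
  if (is.null(y$selections) || length(y$selections) == 0)
    fodm_stop("plan declares no selections", "fodm_parse_error")
  sels <- lapply(y$selections, function(s)
    selection(s$name, s$units, mode = s$mode, parent = s$parent))
  structure_path <- y$structure
  if (!is.null(structure_path) && !file.exists(structure_path)) {
    cand <- file.path(dirname(path), structure_path)
    if (file.exists(cand)) structure_path <- cand
  }
  list(structure = structure_path, model = y$model %||% 1,
       selections = sels)
}

#' Write analysis scores to CSV and/or JSON
#'
#' The CSV carries the convention record (hydrophobicity scale, kernel
#' cutoff, sigma rule, K grid) as `#`-prefixed header comments so every
#' published number is traceable to its settings; the JSON embeds the same
#' record as a field, with raw (unrounded) K values.
#'
#' @param analysis a [analyze()] result.
#' @param csv,json output paths (either may be `NULL`).
#' @return invisibly, the score data frame.
#' @export
write_scores <- function(analysis, csv = NULL, json = NULL) {
  stopifnot(inherits(analysis, "fod_analysis"))
  df <- analysis$scores
  if (!is.null(csv)) {
    con <- file(csv, open = "wt")
    on.exit(close(con), add = TRUE)
    conv <- analysis$conventions
    writeLines(sprintf("# fodm conventions: %s",
                       paste(names(conv), unlist(conv), sep = "=",
                             collapse = " ")), con)
    out <- df
    num <- vapply(out, is.numeric, logical(1)) & names(out) != "n"
    out[num] <- lapply(out[num], function(v) sprintf("%.6g", v))
    write.csv(out, con, row.names = FALSE, quote = FALSE)
  }
  if (!is.null(json))
    jsonlite::write_json(
      list(conventions = analysis$conventions, scores = df),
      json, auto_unbox = TRUE, digits = NA, na = "null", pretty = TRUE)
  invisible(df)
}
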