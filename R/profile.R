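#' Hydrophobicity profile
#'
#' A profile is a normalised per-residue hydrophobicity distribution: a
#' numeric vector of non-negative values summing to 1, tagged with the role
#' it plays in the model (`"T"` theoretical, `"O"` observed, `"R"` uniform
#' reference, `"M"` environment-modified).
#'
#' @param values numeric vector of non-negative weights (normalised to sum 1
#'   unless `normalize = FALSE`).
#' @param role one of `"T"`, `"O"`, `"R"`, `"M"`.
#' @param selection optional name of the residue selection the profile
#'   belongs to.
#' @param normalize divide by the sum (default `TRUE`).
#' @return a numeric vector of class `"fod_profile"` with attributes `role`
#'   and `selection`.
#' @examples
#' fod_profile(c(2, 1, 1), role = "O")
#' @export
fod_profile <- function(values, role = c("T", "O", "R", "M"),
                        selection = NULL, normalize = TRUE) {
  role <- match.arg(role)
  values <- as.numeric(values)
  if (length(values) < 1L)
    fodm_stop("profile must contain at least one value", "fodm_value_error")
  if (any(!is.finite(values)) || any(values < 0))
    fodm_stop("profile values must be finite and non-negative",
              "fodm_value_error")
  if (normalize) {
    s <- sum(values)
    if (s <= 0)
      fodm_stop("profile values sum to zero; cannot normalize",
                "fodm_numeric_error")
    values <- values / s
  }
  structure(values, role = role, selection = selection,
            class = "fod_profile")
}

#' @export
print.fod_profile <- function(x, ...) {
  cat(sprintf("<fod_profile %s> n = %d%s\n", attr(x, "role"), length(x),
              if (!is.null(attr(x, "selection")))
                paste0(", selection: ", attr(x, "selection")) else ""))
  print(as.numeric(x), ...)
  invisible(x)
}

profile_values <- function(p) as.numeric(p)

#' Uniform reference profile
#'
#' The reference distribution R assigns every residue the same weight 1/n;
#' it represents the complete absence of hydrophobicity differentiation.
#'
#' @param n number of residues (>= 1).
#' @return an R-role [fod_profile] of length `n` with all entries `1/n`.
#' @examples
#' r_profile(4)
#' @export
r_profile <- function(n) {
  if (length(n) != 1L || !is.finite(n) || n < 1)
    fodm_stop("n must be a single integer >= 1", "fodm_value_error")
  n <- as.integer(n)
  fod_profile(rep(1 / n, n), role = "R", normalize = FALSE)
}
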