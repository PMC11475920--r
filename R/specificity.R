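#' Select candidate human-associated phages
#'
#' A phage is a candidate when its horizontal genome coverage is strictly
#' above the threshold (default 40%) in every designated human pool.
#'
#' @param mat Coverage matrix (phages x pools), percent.
#' @param human_cols Names of the human pool columns.
#' @param threshold Coverage threshold in percent (strict `>`).
#' @return Character vector of candidate phage ids.
#' @export
select_candidates <- function(mat, human_cols, threshold = 40) {
  check_cols(mat, human_cols)
  sub <- mat[, human_cols, drop = FALSE]
  rownames(mat)[apply(sub > threshold, 1, all)]
}

#' Classify phages as human-specific
#'
#' Implements the human-specificity decision rule on a horizontal-coverage
#' matrix. Candidates (coverage above the threshold in every human pool) are
#' classified by the number of animal pools in which they also exceed the
#' threshold: none -> `HIGH` (highly human-specific), all -> `EXCLUDED`
#' (present across animal pools), otherwise `QUITE` (quite human-specific,
#' present in some but not all animal pools). Phages failing the human
#' threshold are `NOT_CANDIDATE` regardless of the animal columns. All
#' comparisons are strict (`>`); a value of exactly `threshold` counts as
#' absent.
#'
#' @param mat Coverage matrix (phages x pools), percent in `[0, 100]`.
#' @param human_cols Names of the human pool columns.
#' @param animal_cols Names of the animal pool columns.
#' @param threshold Coverage threshold in percent (default 40).
#' @return data.frame with columns `phage`, `class` (factor HIGH / QUITE /
#'   EXCLUDED / NOT_CANDIDATE) and `n_animal_pools_present`.
#' @export
classify_specificity <- function(mat, human_cols, animal_cols, threshold = 40) {
  check_cols(mat, human_cols)
  if (length(animal_cols) == 0) stop("at least one animal pool column required")
  check_cols(mat, animal_cols)
  stopifnot(threshold > 0, threshold < 100)
  candidates <- select_candidates(mat, human_cols, threshold)
  n_animal <- apply(mat[, animal_cols, drop = FALSE] > threshold, 1, sum)
  cls <- ifelse(!rownames(mat) %in% candidates, "NOT_CANDIDATE",
         ifelse(n_animal == 0, "HIGH",
         ifelse(n_animal == length(animal_cols), "EXCLUDED", "QUITE")))
  data.frame(phage = rownames(mat),
             class = factor(cls, levels = c("HIGH", "QUITE", "EXCLUDED",
                                            "NOT_CANDIDATE")),
             n_animal_pools_present = as.integer(n_animal),
             stringsAsFactors = FALSE)
}

check_cols <- function(mat, cols) {
  missing <- setdiff(cols, colnames(mat))
  if (length(missing)) stop("unknown pool column: ", missing[1])
  invisible(TRUE)
}

#' Exact Mann-Whitney U test by full enumeration
#'
#' Computes `U = max(U_x, U_y)`, where `U_x` counts pairs with `x_i > y_j`
#' plus 0.5 per tie, and an exact two-sided p-value as twice the one-sided
#' tail probability `Pr(U_x >= U)` under uniform relabeling, enumerated over
#' all `choose(n_x + n_y, n_x)` group assignments of the pooled values
#' (capped at 1). Ties are handled by midranks. For two groups of sizes 4 and
#' 5 with complete separation this gives U = 20 and p = 2/126.
#'
#' @param x,y Numeric value vectors (each of size 1 to 12; the exact
#'   enumeration regime).
#' @return List with elements `U` and `p_value`.
#' @export
#' @examples
#' mann_whitney_exact(c(10, 11, 12, 13), c(1, 2, 3, 4, 5))
mann_whitney_exact <- function(x, y) {
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  if (length(x) > 12 || length(y) > 12) {
    stop("exact enumeration supports group sizes up to 12")
  }
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))                       # midranks handle ties as 0.5 counts
  ux <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  uy <- nx * ny - ux
  u <- max(ux, uy)
  # null distribution of U_x over all labelings of the pooled sample
  ux_all <- combn(nx + ny, nx, FUN = function(i) sum(r[i])) - nx * (nx + 1) / 2
  p <- min(1, 2 * mean(ux_all >= u - 1e-9))
  list(U = u, p_value = p)
}
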