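#' Pauli degeneration score
#'
#' Sums the four components of the Pauli semiquantitative histology
#' classification of meniscus degeneration and assigns the grade bin.
#' Surface integrity is scored 0-3 for each of the femoral, tibial and
#' inner surfaces and is supplied here as their total (0-9); cellularity,
#' collagen organization/alignment and matrix (Safranin-O) staining
#' intensity are each scored 0-3, giving a sum score of 0-18.
#'
#' Grade bins: sum 0-4 -> Grade I (grossly intact), 5-9 -> Grade II (early
#' degenerative), 10-14 -> Grade III (moderately degenerative), 15-18 ->
#' Grade IV (severely degenerative). Grades III and IV are collapsed into
#' the ">=III" group for cohort trichotomization.
#'
#' @param surface total surface-integrity score, integer 0-9
#' @param cellularity cellularity score, integer 0-3
#' @param collagen collagen organization score, integer 0-3
#' @param staining matrix staining score, integer 0-3
#' @return A data.frame with columns `surface`, `cellularity`, `collagen`,
#'   `staining`, `sum`, `grade` (factor I-IV) and `group` (factor
#'   I / II / >=III). Inputs are vectorized.
#' @examples
#' pauli_score(1, 0, 1, 2)  # sum 4, Grade I
#' pauli_score(7, 1, 2, 2)  # sum 12, Grade III, group >=III
#' @export
pauli_score <- function(surface, cellularity, collagen, staining) {
  comp <- list(surface = surface, cellularity = cellularity,
               collagen = collagen, staining = staining)
  caps <- c(surface = 9, cellularity = 3, collagen = 3, staining = 3)
  n <- unique(lengths(comp))
  if (length(n) != 1L)
    stop("component score vectors must have equal length")
  for (nm in names(comp)) {
    x <- comp[[nm]]
    if (any(!is.finite(x) | x != round(x) | x < 0 | x > caps[[nm]]))
      stop(sprintf("component '%s' must be an integer in 0-%d", nm, caps[[nm]]))
  }
  s <- surface + cellularity + collagen + staining
  grade <- pauli_grade(s)
  data.frame(surface = surface, cellularity = cellularity,
             collagen = collagen, staining = staining, sum = s,
             grade = grade, group = pauli_group(grade))
}

#' Pauli grade from a sum score
#'
#' @param sum_score integer vector of Pauli sum scores (0-18)
#' @return factor with levels I, II, III, IV
#' @export
pauli_grade <- function(sum_score) {
  if (any(!is.finite(sum_score) | sum_score < 0 | sum_score > 18))
    stop("Pauli sum score must lie in 0-18")
  cut(sum_score, breaks = c(-0.5, 4.5, 9.5, 14.5, 18.5),
      labels = c("I", "II", "III", "IV"))
}

#' Collapse Pauli grades into the trichotomized subgroup
#'
#' Grades III and IV are pooled (">=III"); I and II are kept.
#'
#' @param grade factor or character vector with values I, II, III, IV
#' @return factor with levels I, II, >=III
#' @export
pauli_group <- function(grade) {
  g <- as.character(grade)
  if (!all(g %in% c("I", "II", "III", "IV")))
    stop("grade must be one of I, II, III, IV")
  factor(ifelse(g %in% c("III", "IV"), ">=III", g),
         levels = c("I", "II", ">=III"))
}
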