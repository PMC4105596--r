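#' Express a diploid trait
#'
#' Trait values are the arithmetic mean of the two alleles carried, so both
#' traits live on the same \[0, 1\] scale as their alleles.
#'
#' @param maternal,paternal Allelic values in \[0, 1\]; vectors are paired
#'   elementwise.
#' @return `(maternal + paternal) / 2`.
#' @examples
#' express_trait(0.2, 0.8)  # 0.5
#' @export
express_trait <- function(maternal, paternal) {
  check_alleles(maternal, "maternal")
  check_alleles(paternal, "paternal")
  (maternal + paternal) / 2
}

#' Draw a gamete allele from a diploid pair
#'
#' Mendelian segregation: each parental allele is transmitted with equal
#' probability. Vectorised over pairs; one draw per pair.
#'
#' @param maternal,paternal The two allelic values of the parental pair.
#' @return One of the two inputs per pair, each with probability 1/2.
#' @export
draw_gamete_allele <- function(maternal, paternal) {
  check_alleles(maternal, "maternal")
  check_alleles(paternal, "paternal")
  n <- max(length(maternal), length(paternal))
  maternal <- rep_len(maternal, n)
  paternal <- rep_len(paternal, n)
  ifelse(runif(n) < 0.5, maternal, paternal)
}

#' Mutate transmitted alleles
#'
#' With probability `rate` (independently per allele) the transmitted copy is
#' replaced by a fresh Uniform(0, 1) draw, independent of its current value;
#' otherwise it is passed on unchanged.
#'
#' @param allele Allelic values in \[0, 1\].
#' @param rate Per-allele mutation probability.
#' @return The (possibly mutated) allelic values.
#' @export
apply_mutation <- function(allele, rate) {
  check_alleles(allele, "allele")
  if (!is.numeric(rate) || length(rate) != 1 || rate < 0 || rate > 1)
    stop("'rate' must be a single probability in [0, 1]")
  hit <- runif(length(allele)) < rate
  if (any(hit)) allele[hit] <- runif(sum(hit))
  allele
}

#' Build an offspring genome
#'
#' One allele per trait comes from the mother's pair and one from the stored
#' pair of the male she mated with; each transmitted copy is then subject to
#' mutation at the trait's rate (`viability_mutation` for viability alleles,
#' `preference_mutation` for preference alleles). The maternal/paternal slot
#' assignment is fixed at birth.
#'
#' @param mother_genome Named numeric vector with elements
#'   `viability_maternal`, `viability_paternal`, `preference_maternal`,
#'   `preference_paternal`: the mother's own alleles.
#' @param stored_paternal Named numeric vector with the same four elements:
#'   the alleles of the mated male, as stored at mating.
#' @param p A `sim_params` object (supplies the two mutation rates).
#' @return Named numeric vector of the four offspring alleles.
#' @export
make_offspring_genome <- function(mother_genome, stored_paternal, p) {
  slots <- c("viability_maternal", "viability_paternal",
             "preference_maternal", "preference_paternal")
  for (g in list(mother_genome, stored_paternal)) {
    if (!all(slots %in% names(g)))
      stop("genome must carry the four named alleles: ",
           paste(slots, collapse = ", "))
    if (anyNA(g[slots]))
      stop("incomplete stored alleles: all four allelic values are required")
    check_alleles(as.numeric(g[slots]), "genome")
  }
  vm <- p$viability_mutation
  pm <- p$preference_mutation
  out <- c(
    viability_maternal = apply_mutation(
      draw_gamete_allele(mother_genome[["viability_maternal"]],
                         mother_genome[["viability_paternal"]]), vm),
    viability_paternal = apply_mutation(
      draw_gamete_allele(stored_paternal[["viability_maternal"]],
                         stored_paternal[["viability_paternal"]]), vm),
    preference_maternal = apply_mutation(
      draw_gamete_allele(mother_genome[["preference_maternal"]],
                         mother_genome[["preference_paternal"]]), pm),
    preference_paternal = apply_mutation(
      draw_gamete_allele(stored_paternal[["preference_maternal"]],
                         stored_paternal[["preference_paternal"]]), pm))
  out
}

check_alleles <- function(x, what) {
  if (!is.numeric(x))
    stop("'", what, "' must be numeric")
  bad <- !is.na(x) & (x < 0 | x > 1)
  if (any(bad))
    stop("'", what, "' allelic values must lie in [0, 1]; offending value: ",
         x[bad][1])
  if (anyNA(x))
    stop("'", what, "' contains missing allelic values")
  invisible(x)
}
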