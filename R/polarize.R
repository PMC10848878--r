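#' Polarize SV alleles with two outgroup genotypes
#'
#' Assigns the ancestral state of each locus from two outgroup
#' individuals genotyped at the same loci.  A locus is polarized only when
#' both outgroups are homozygous for the same allele: both hom-ref gives
#' `ancestral = REF`, both hom-alt gives `ancestral = ALT`; disagreement,
#' heterozygosity or missingness leaves the locus `UNPOLARIZED`.  The rule
#' is symmetric in the two outgroups.
#'
#' Polarization reclassifies the called SV into a mutation type.  A call
#' is made relative to the reference assembly, so a "deletion" whose ALT
#' (deleted) allele is ancestral is actually an insertion in the reference
#' lineage; analogously for duplications and inversions:
#'
#' | svtype | ancestral REF | ancestral ALT |
#' |--------|---------------|---------------|
#' | DEL    | `TRUE_DELETION` | `INSERTION` |
#' | DUP    | `COPY_GAIN`     | `COPY_LOSS_IN_REFERENCE` |
#' | INV    | `INVERSION_DERIVED` | `INVERSION_ANCESTRAL_REF` |
#'
#' @param x An [SVCohort-class].
#' @param outgroups Integer matrix of outgroup genotypes with exactly 2
#'   rows (outgroup individuals) and one column per locus of `x` (ALT
#'   dosage 0/1/2, `NA` = missing), or the transpose.
#' @return A `data.frame` with `variant_id`, `ancestral`
#'   (`REF`/`ALT`/`UNPOLARIZED`), `derived_is_reference` (`TRUE` when the
#'   ancestral allele is ALT) and `mutation_class`.
#' @export
polarize <- function(x, outgroups) {
  outgroups <- .checkOutgroups(outgroups, nrow(x))
  o1 <- outgroups[1, ]; o2 <- outgroups[2, ]
  anc <- rep("UNPOLARIZED", nrow(x))
  anc[!is.na(o1) & !is.na(o2) & o1 == 0L & o2 == 0L] <- "REF"
  anc[!is.na(o1) & !is.na(o2) & o1 == 2L & o2 == 2L] <- "ALT"
  type <- svType(x)
  cls_map <- rbind(DEL = c(REF = "TRUE_DELETION", ALT = "INSERTION"),
                   DUP = c(REF = "COPY_GAIN", ALT = "COPY_LOSS_IN_REFERENCE"),
                   INV = c(REF = "INVERSION_DERIVED",
                           ALT = "INVERSION_ANCESTRAL_REF"))
  cls <- rep("UNPOLARIZED", nrow(x))
  pol <- anc != "UNPOLARIZED"
  cls[pol] <- cls_map[cbind(type[pol], anc[pol])]
  data.frame(variant_id = variantIds(x),
             ancestral = factor(anc, levels = c("REF", "ALT", "UNPOLARIZED")),
             derived_is_reference = anc == "ALT",
             mutation_class = cls, stringsAsFactors = FALSE)
}

.checkOutgroups <- function(outgroups, n_loci) {
  if (!is.matrix(outgroups)) stop("outgroups must be a 2-row matrix")
  if (nrow(outgroups) != 2 && ncol(outgroups) == 2)
    outgroups <- t(outgroups)
  if (nrow(outgroups) != 2)
    stop("exactly two outgroup individuals are required, got ",
         nrow(outgroups))
  if (ncol(outgroups) != n_loci)
    stop("outgroup genotypes cover ", ncol(outgroups),
         " loci but the cohort has ", n_loci)
  outgroups
}

#' Loci where the reference allele is ancestral
#'
#' The load analyses are restricted to loci at which the reference
#' assembly carries the ancestral allele, so that hom-ALT genotypes are
#' homozygous-derived and annotation (built on the reference) is not
#' confounded by derived sequence present in the reference.
#'
#' @param polarized Output of [polarize()].
#' @return Character vector of variant ids with `ancestral == "REF"`.
#' @export
referenceAncestralSubset <- function(polarized) {
  polarized$variant_id[polarized$ancestral == "REF"]
}
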