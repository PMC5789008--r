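# Canonical panel of the nine dopaminergic polymorphisms the index is built
# from. `canonical_allele` is the allele the composite is expressed on (the
# allele named in the published first-component loading list); `loading` is
# that published loading, used as the generator's default latent weights;
# `base_freq` is a plausible worldwide baseline frequency for the canonical
# allele, used only by the synthetic generator.
.poly_table <- data.frame(
  id               = c("rs28363170", "rs1800497", "rs1079597", "rs1800498",
                       "rs6275", "rs6277", "rs1799732", "rs6280", "rs1800955"),
  gene             = c("DAT1", "DRD2", "DRD2", "DRD2", "DRD2", "DRD2",
                       "DRD2", "DRD3", "DRD4"),
  label            = c("40-bp VNTR (9R carrier)", "Taq1A", "Taq1B", "Taq1D",
                       "C939T", "C957T", "-141C ins/del", "Ser9Gly", "C-521T"),
  canonical_allele = c("9R", "A1", "B1", "D1", "C", "C", "ins", "ser", "T"),
  other_allele     = c("10R", "A2", "B2", "D2", "T", "T", "del", "gly", "C"),
  loading          = c(0.75, -0.89, -0.67, 0.86, 0.34, -0.87, 0.44, 0.50, 0.63),
  base_freq        = c(0.45, 0.35, 0.30, 0.65, 0.60, 0.55, 0.85, 0.60, 0.45),
  stringsAsFactors = FALSE
)

# Common literature aliases accepted wherever a polymorphism id is expected.
.poly_aliases <- c(
  DAT1_VNTR    = "rs28363170",
  DRD2_Taq1A   = "rs1800497",
  DRD2_Taq1B   = "rs1079597",
  DRD2_Taq1D   = "rs1800498",
  DRD2_C939T   = "rs6275",
  DRD2_C957T   = "rs6277",
  DRD2_141C    = "rs1799732",
  DRD3_Ser9Gly = "rs6280",
  DRD4_C521T   = "rs1800955"
)

#' The canonical dopaminergic polymorphism panel
#'
#' Returns the nine-polymorphism panel (one VNTR coded by 9-repeat carrier
#' status, eight SNPs) the gene-system index is defined over, with the
#' canonical allele each frequency must be expressed on, the published
#' first-component loading used as the generator default, and a baseline
#' worldwide frequency used by [simulate_dataset()].
#'
#' @return A data frame with columns `id` (rs identifier), `gene`, `label`,
#'   `canonical_allele`, `other_allele`, `loading`, `base_freq`.
#' @export
#' @examples
#' dopamine_polymorphisms()
dopamine_polymorphisms <- function() {
  .poly_table
}

# Resolve ids (rs numbers or aliases) to canonical rs ids; error on unknowns.
resolve_polymorphism <- function(id) {
  id <- as.character(id)
  out <- ifelse(id %in% .poly_table$id, id, unname(.poly_aliases[id]))
  bad <- unique(id[is.na(out)])
  if (length(bad)) {
    stop("unknown polymorphism id(s): ", paste(bad, collapse = ", "),
         "; expected one of ", paste(.poly_table$id, collapse = ", "),
         " (or aliases ", paste(names(.poly_aliases), collapse = ", "), ")",
         call. = FALSE)
  }
  out
}
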