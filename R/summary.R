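#' Round half-up
#'
#' Decimal rounding with the half-up convention used for the printed
#' summary values (base R's `round` rounds half to even).
#'
#' @param x numeric.
#' @param digits decimals.
#' @return rounded numeric.
#' @export
roundHalfUp <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

.needField <- function(records, field) {
  if (!field %in% names(records)) {
    stop("no field '", field, "' in the specimen table")
  }
}

#' Species mean of a specimen field
#'
#' Arithmetic mean over the specimens of one species, optionally excluding
#' the reference specimen (whose reads built the reference genome, so its
#' mapped fractions are trivially ~100%), rounded half-up.
#'
#' @param records specimen data.frame (see [loadSpecimenFixture()]).
#' @param field column name.
#' @param species species label.
#' @param excludeReference drop `is_reference` records.
#' @param digits decimals for half-up rounding.
#' @return the rounded mean.
#' @examples
#' fx <- loadSpecimenFixture()
#' speciesMean(fx, "mapped_noncoding_pct", "C_cecrops") # 88
#' speciesMean(fx, "mapped_noncoding_pct", "C_isobeon") # 83
#' @export
speciesMean <- function(records, field, species, excludeReference = TRUE,
                        digits = 0) {
  .needField(records, field)
  sel <- records$species == species
  if (excludeReference) sel <- sel & !records$is_reference
  if (!any(sel)) stop("no matching records for species '", species, "'")
  roundHalfUp(mean(records[[field]][sel]), digits)
}

#' Range of a specimen field
#'
#' @param records specimen data.frame.
#' @param field column name.
#' @param digits decimals for half-up rounding.
#' @return named numeric `c(min = ., max = .)`.
#' @examples
#' fieldRange(loadSpecimenFixture(), "het_pct", 1) # 1.2 2.0
#' @export
fieldRange <- function(records, field, digits = 2) {
  .needField(records, field)
  if (nrow(records) == 0) stop("no records")
  v <- records[[field]]
  c(min = roundHalfUp(min(v), digits), max = roundHalfUp(max(v), digits))
}

#' Between-species comparison of mapped fractions
#'
#' Two-sample t-test of the mapped non-coding fraction between the species
#' that provided the reference genome (its reference specimen excluded)
#' and the other species. Both the pooled-variance and the Welch variant
#' are reported with one- and two-sided p-values; the one-sided
#' alternative is that the reference-genome species maps better. Groups
#' with zero pooled variance are flagged degenerate (p reported as the 0/1
#' limit with a warning).
#'
#' @param records specimen data.frame.
#' @param field column to compare.
#' @return list with `group_means`, `pooled` and `welch` sublists
#'   (`t`, `df`, `p_two_sided`, `p_one_sided`) and `degenerate`.
#' @export
compareSpeciesMapping <- function(records,
                                  field = "mapped_noncoding_pct") {
  .needField(records, field)
  recs <- records[!records$is_reference, , drop = FALSE]
  ref_species <- records$species[records$is_reference]
  species <- unique(records$species)
  if (length(species) != 2) stop("expected exactly 2 species")
  ref_sp <- if (length(ref_species)) ref_species[1] else sort(species)[1]
  other_sp <- setdiff(species, ref_sp)
  x <- recs[[field]][recs$species == ref_sp]
  y <- recs[[field]][recs$species == other_sp]
  if (length(x) < 2 || length(y) < 2) {
    stop("each species needs at least 2 non-reference specimens")
  }
  means <- c(mean(x), mean(y))
  names(means) <- c(ref_sp, other_sp)
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (means[1] == means[2]) {
      res <- list(t = 0, df = length(x) + length(y) - 2,
                  p_two_sided = 1, p_one_sided = 0.5)
      return(list(group_means = means, pooled = res, welch = res,
                  degenerate = TRUE))
    }
    warning("zero within-group variance with unequal means; ",
            "p reported as the 0 limit")
    res <- list(t = Inf * sign(means[1] - means[2]),
                df = length(x) + length(y) - 2,
                p_two_sided = 0, p_one_sided = 0)
    return(list(group_means = means, pooled = res, welch = res,
                degenerate = TRUE))
  }
  one_sided <- function(tt) {
    # one-sided p for the alternative mean(x) > mean(y)
    stats::pt(tt$statistic, tt$parameter, lower.tail = FALSE)
  }
  pl <- t.test(x, y, var.equal = TRUE)
  wl <- t.test(x, y)
  list(
    group_means = means,
    pooled = list(
      t = unname(pl$statistic), df = unname(pl$parameter),
      p_two_sided = pl$p.value, p_one_sided = unname(one_sided(pl))
    ),
    welch = list(
      t = unname(wl$statistic), df = unname(wl$parameter),
      p_two_sided = wl$p.value, p_one_sided = unname(one_sided(wl))
    ),
    degenerate = FALSE
  )
}

#' Heterozygosity-latitude association
#'
#' Pearson correlation between genome-wide heterozygosity and collection
#' latitude (with the usual t-test p-value, two-sided and one-sided in the
#' observed direction) plus the Spearman rank correlation as a
#' distribution-free companion.
#'
#' @param records specimen data.frame with `latitude` and `het_pct`.
#' @return list with `pearson` (`r`, `t`, `df`, `p_two_sided`,
#'   `p_one_sided`) and `spearman` (`rho`, `p_two_sided`, `p_one_sided`).
#' @export
hetLatitudeAssociation <- function(records) {
  .needField(records, "latitude")
  .needField(records, "het_pct")
  ok <- !is.na(records$latitude) & !is.na(records$het_pct)
  lat <- records$latitude[ok]
  het <- records$het_pct[ok]
  if (length(lat) < 3) stop("need at least 3 records with latitude")
  if (stats::var(lat) == 0 || stats::var(het) == 0) {
    stop("zero variance in latitude or heterozygosity")
  }
  pe <- cor.test(lat, het)
  sp <- suppressWarnings(cor.test(lat, het, method = "spearman",
                                  exact = FALSE))
  list(
    pearson = list(
      r = unname(pe$estimate), t = unname(pe$statistic),
      df = unname(pe$parameter), p_two_sided = pe$p.value,
      p_one_sided = pe$p.value / 2
    ),
    spearman = list(
      rho = unname(sp$estimate), p_two_sided = sp$p.value,
      p_one_sided = sp$p.value / 2
    )
  )
}

#' Full specimen summary report
#'
#' Species means of the mapped fractions (with and without the reference
#' specimen), heterozygosity ranges, the between-species mapping
#' comparison, and the heterozygosity-latitude association.
#'
#' @param records specimen data.frame.
#' @return nested list (a `SummaryReport`).
#' @export
summarizeSpecimens <- function(records) {
  species <- sort(unique(records$species))
  means <- lapply(c(TRUE, FALSE), function(excl) {
    sapply(species, function(s) {
      c(
        mapped_noncoding = speciesMean(records, "mapped_noncoding_pct", s,
                                       excludeReference = excl, digits = 0),
        mapped_coding = speciesMean(records, "mapped_coding_pct", s,
                                    excludeReference = excl, digits = 0)
      )
    })
  })
  list(
    species_means = means[[1]],
    species_means_with_reference = means[[2]],
    het_range = fieldRange(records, "het_pct", 1),
    het_coding_range = fieldRange(records, "het_coding_pct", 2),
    mapping_comparison = compareSpeciesMapping(records),
    het_latitude = hetLatitudeAssociation(records)
  )
}
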