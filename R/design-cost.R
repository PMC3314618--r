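# design_cost: closed-form experiment-design combinatorics, equimolar
# pooling arithmetic, and the Sanger-vs-pyrosequencing cost model.

#' Cost scenario for the Sanger-vs-454 comparison
#'
#' Defaults reproduce the published grid: 3200 individual loci, $4.00 per
#' Sanger read, forward + reverse direct sequencing, five reads per cloned
#' locus, $12.50 cloning per sample, $125 of conventional primers, and
#' $12,137 primers + $12,423 full-plate sequencing on the 454 side.
#'
#' @param n_loci_total Individual x locus sequencing targets.
#' @param sanger_price_per_read Price per Sanger read.
#' @param reads_per_direct_locus Direct reads per locus (F + R = 2).
#' @param frac_cloned Fraction of loci needing cloning, in `[0, 1]`.
#' @param reads_per_clone Reads sequenced per cloned locus.
#' @param cloning_cost_per_sample Cloning cost added per cloned sample.
#' @param primer_cost Conventional primer cost.
#' @param primer_cost_454 Tagged fusion-primer synthesis cost.
#' @param plate_cost_454 Full-plate sequencing cost (library QC,
#'   quantification and emPCR included).
#' @return A `cost_scenario` list.
#' @export
cost_scenario <- function(n_loci_total = 3200, sanger_price_per_read = 4,
                          reads_per_direct_locus = 2, frac_cloned = 0,
                          reads_per_clone = 5, cloning_cost_per_sample = 12.5,
                          primer_cost = 125, primer_cost_454 = 12137,
                          plate_cost_454 = 12423) {
  s <- list(n_loci_total = n_loci_total,
            sanger_price_per_read = sanger_price_per_read,
            reads_per_direct_locus = reads_per_direct_locus,
            frac_cloned = frac_cloned, reads_per_clone = reads_per_clone,
            cloning_cost_per_sample = cloning_cost_per_sample,
            primer_cost = primer_cost, primer_cost_454 = primer_cost_454,
            plate_cost_454 = plate_cost_454)
  money <- unlist(s[c("sanger_price_per_read", "cloning_cost_per_sample",
                      "primer_cost", "primer_cost_454", "plate_cost_454")])
  stopifnot(all(money >= 0), s$frac_cloned >= 0, s$frac_cloned <= 1,
            s$n_loci_total >= 0)
  class(s) <- "cost_scenario"
  s
}

#' Total Sanger sequencing cost
#'
#' Every locus is direct-sequenced F + R; the cloned fraction keeps that
#' cost and adds cloning plus the per-clone reads on top:
#' `primer + n * reads_direct * price + frac * n * (cloning + reads_clone * price)`.
#'
#' @param s A [cost_scenario()].
#' @return Total cost.
#' @export
sanger_cost <- function(s) {
  s$primer_cost +
    s$n_loci_total * s$reads_per_direct_locus * s$sanger_price_per_read +
    s$frac_cloned * s$n_loci_total *
      (s$cloning_cost_per_sample + s$reads_per_clone * s$sanger_price_per_read)
}

#' Total targeted-454 cost
#'
#' Tagged primer synthesis plus the full sequencing plate.
#'
#' @param s A [cost_scenario()].
#' @return Total cost.
#' @export
cost_454 <- function(s) s$primer_cost_454 + s$plate_cost_454

#' Experimental design specification
#'
#' @param n_individuals Individuals per population per species.
#' @param n_species Species multiplexed together.
#' @param n_loci Loci per species.
#' @param n_populations Populations (gasketed plate regions).
#' @param mass_target_ng PCR product pooled per amplicon (ng).
#' @return A `design_spec` list.
#' @export
design_spec <- function(n_individuals = 20, n_species = 2, n_loci = 5,
                        n_populations = 16, mass_target_ng = 0.5) {
  d <- list(n_individuals = n_individuals, n_species = n_species,
            n_loci = n_loci, n_populations = n_populations,
            mass_target_ng = mass_target_ng)
  stopifnot(d$n_individuals >= 1, d$n_species >= 1, d$n_loci >= 1,
            d$n_populations >= 1, d$mass_target_ng > 0)
  class(d) <- "design_spec"
  d
}

#' Number of tagged fusion primers to synthesise
#'
#' Two labelled primers (F and R) per individual, species and locus:
#' `2 * n_individuals * n_species * n_loci`.
#'
#' @param d A [design_spec()].
#' @return Primer count.
#' @export
primer_count <- function(d) 2 * d$n_individuals * d$n_species * d$n_loci

#' Number of individual sequencing targets
#'
#' `n_populations * n_individuals * n_species * n_loci`.
#'
#' @param d A [design_spec()].
#' @return Individual x locus count.
#' @export
loci_count <- function(d) {
  d$n_populations * d$n_individuals * d$n_species * d$n_loci
}

#' Equimolar pooling volume
#'
#' Volume of a PCR reaction contributing the target mass at the measured
#' concentration: `mass_target / conc`.
#'
#' @param conc_ng_per_ul Measured concentration (ng/uL); must be positive.
#' @param mass_target_ng Target mass per amplicon (default 0.5 ng).
#' @return Volume in uL.
#' @export
pooling_volume <- function(conc_ng_per_ul, mass_target_ng = 0.5) {
  if (any(conc_ng_per_ul <= 0)) stop("concentration must be positive")
  mass_target_ng / conc_ng_per_ul
}

#' Probability that the majority of k clonal reads is correct
#'
#' For an odd sample of `k` reads each independently correct with
#' probability `p`: `sum_{i > k/2} C(k, i) p^i (1-p)^(k-i)`. At p = 0.9
#' (an error rate an order of magnitude above the platform's ~1%), five
#' reads already give over 99% confidence in the majority call.
#'
#' @param k_reads Odd number of reads.
#' @param p_correct Per-read probability of being correct.
#' @return The majority-correct probability.
#' @export
majority_confidence <- function(k_reads, p_correct) {
  if (k_reads %% 2 == 0) {
    stop("k_reads must be odd: a majority is undefined without a tie rule")
  }
  stopifnot(p_correct >= 0, p_correct <= 1)
  pbinom((k_reads - 1) / 2, k_reads, p_correct, lower.tail = FALSE)
}

#' The published cost-comparison grid
#'
#' Convenience wrapper evaluating [sanger_cost()] over cloned fractions
#' and [cost_454()] once.
#'
#' @param frac_cloned Cloned fractions for the Sanger columns.
#' @param s Base [cost_scenario()].
#' @return Data frame: `scenario`, `primer_cost`, `sequencing_cost`,
#'   `total_cost`.
#' @export
cost_table <- function(frac_cloned = c(0, 0.125, 0.25, 0.5),
                       s = cost_scenario()) {
  rows <- list(data.frame(
    scenario = "454", primer_cost = s$primer_cost_454,
    sequencing_cost = s$plate_cost_454, total_cost = cost_454(s),
    stringsAsFactors = FALSE
  ))
  for (f in frac_cloned) {
    si <- s
    si$frac_cloned <- f
    tot <- sanger_cost(si)
    rows[[length(rows) + 1L]] <- data.frame(
      scenario = if (f == 0) "F+R sequencing" else
        sprintf("F+R, %g%% cloned", 100 * f),
      primer_cost = s$primer_cost, sequencing_cost = tot - s$primer_cost,
      total_cost = tot, stringsAsFactors = FALSE
    )
  }
  do.call(rbind, rows)
}
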