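#' Average technical replicates with the >1 Cq outlier rule
#'
#' Technical replicates are averaged as-is when their spread (max - min) is
#' at most 1 Cq. When three or more replicates spread wider, the single
#' replicate farthest from the median is treated as the outlier, dropped,
#' and the rest averaged (ties keep the earlier-listed replicate and drop
#' the later one). Two replicates more than 1 Cq apart have no identifiable
#' outlier: the record is flagged unresolvable and should be excluded.
#'
#' @param reps numeric vector of Cq values (length >= 1).
#' @return list with `mean` (averaged Cq, `NA` if unresolvable), `dropped`
#'   (index of the removed replicate, or `NA`), `unresolvable` (logical).
#' @examples
#' average_tech_reps(c(20.0, 20.1, 20.2))  # plain mean
#' average_tech_reps(c(20.0, 20.1, 23.0))  # drops the third
#' @export
average_tech_reps <- function(reps) {
  if (!length(reps) || anyNA(reps))
    stop_refstab("reps must be a non-empty numeric vector without NA")
  if (length(reps) == 1 || diff(range(reps)) <= 1)
    return(list(mean = mean(reps), dropped = NA_integer_, unresolvable = FALSE))
  if (length(reps) == 2)
    return(list(mean = NA_real_, dropped = NA_integer_, unresolvable = TRUE))
  d <- abs(reps - stats::median(reps))
  # ties broken by keeping earlier-listed replicates (drop the last max)
  drop_idx <- max(which(d == max(d)))
  list(mean = mean(reps[-drop_idx]), dropped = drop_idx, unresolvable = FALSE)
}

#' Collapse a long Cq table over technical replicates
#'
#' Applies [average_tech_reps] per (gene, species, tissue, bio_rep) group.
#' Unresolvable records (two replicates >1 Cq apart) are excluded with a
#' warning.
#'
#' @param cq data.frame with columns `gene`, `species`, `tissue`, `bio_rep`,
#'   `tech_rep`, `cq` (see [read_cq_table]).
#' @return data.frame with one row per biological sample: columns `gene`,
#'   `species`, `tissue`, `bio_rep`, `cq`, `n_reps`, `dropped_rep`.
#' @export
collapse_tech_reps <- function(cq) {
  need <- c("gene", "species", "tissue", "bio_rep", "cq")
  miss <- setdiff(need, names(cq))
  if (length(miss))
    stop_refstab("Cq table lacks column(s): %s", paste(miss, collapse = ", "))
  key <- interaction(cq$gene, cq$species, cq$tissue, cq$bio_rep, drop = TRUE)
  groups <- split(seq_len(nrow(cq)), key)
  rows <- lapply(groups, function(ix) {
    res <- average_tech_reps(cq$cq[ix])
    data.frame(gene = cq$gene[ix[1]], species = cq$species[ix[1]],
               tissue = cq$tissue[ix[1]], bio_rep = cq$bio_rep[ix[1]],
               cq = res$mean, n_reps = length(ix),
               dropped_rep = res$dropped,
               unresolvable = res$unresolvable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (any(out$unresolvable)) {
    warning(sprintf("%d record(s) with 2 technical replicates >1 Cq apart excluded",
                    sum(out$unresolvable)))
    out <- out[!out$unresolvable, , drop = FALSE]
  }
  out$unresolvable <- NULL
  out
}

#' Amplification efficiency from a dilution-series standard curve
#'
#' Fits Cq on log10(relative concentration) by ordinary least squares; the
#' amplification efficiency is `E = 10^(1/-slope)` (E = 2 means perfect
#' per-cycle doubling, reported as 100%). Dilution factors are entered as
#' relative concentrations (1, 0.25, 0.0625, ...), not step indices.
#'
#' @param dilution numeric vector of relative concentrations (> 0).
#' @param cq matched Cq values.
#' @return list of class `dilution_fit`: `slope`, `efficiency` (base E),
#'   `percent` ((E-1)*100), `r_squared`, `n`.
#' @examples
#' # perfect doubling: Cq rises 2 cycles per 1:4 dilution step
#' d <- 4^-(0:4)
#' fit_efficiency(d, 20 - log2(d))$efficiency  # 2.0
#' @export
fit_efficiency <- function(dilution, cq) {
  if (length(dilution) != length(cq))
    stop_refstab("dilution and cq lengths differ")
  if (length(dilution) < 3)
    stop_refstab("need at least 3 dilution points, got %d", length(dilution))
  if (any(dilution <= 0)) stop_refstab("dilutions must be positive")
  fit <- stats::lm(cq ~ log10(dilution))
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop_refstab("non-negative standard-curve slope (%.3g): assay failure", slope)
  eff <- 10^(1 / -slope)
  sst <- sum((cq - mean(cq))^2)
  r2 <- if (sst > 0) 1 - sum(stats::residuals(fit)^2) / sst else NA_real_
  structure(list(slope = slope, efficiency = eff, percent = (eff - 1) * 100,
                 r_squared = r2, n = length(dilution)),
            class = "dilution_fit")
}

#' @export
print.dilution_fit <- function(x, ...) {
  cat(sprintf("standard curve: slope %.4f, E = %.3f (%.1f%%), R^2 = %.4f, n = %d\n",
              x$slope, x$efficiency, x$percent, x$r_squared, x$n))
  invisible(x)
}

#' Efficiency- and calibrator-normalized relative expression
#'
#' Relative expression of gene g in sample s is
#' `E_g ^ (Cq_calibrator - Cq_sample)`, where the calibrator Cq for a gene
#' is its Cq in the designated calibrator sample (a fixed sample run
#' alongside every batch to make Cq values comparable). Equals 1 when a
#' sample's Cq matches the calibrator's.
#'
#' @param cq collapsed Cq data.frame (see [collapse_tech_reps]) with columns
#'   `gene`, `species`, `tissue`, `bio_rep`, `cq`.
#' @param efficiencies named numeric vector, base-E amplification efficiency
#'   per gene; every gene in `cq` must be covered.
#' @param calibrator list identifying the calibrator biological sample, with
#'   elements `species`, `tissue`, `bio_rep` (e.g.
#'   `list(species = "luteus", tissue = "leaf", bio_rep = 1)`); each gene's
#'   calibrator Cq is its own Cq in that sample. Alternatively a named
#'   numeric vector of per-gene calibrator Cq values.
#' @return data.frame with columns of `cq` plus `rel_expr`.
#' @export
relative_expression <- function(cq, efficiencies, calibrator) {
  miss <- setdiff(unique(cq$gene), names(efficiencies))
  if (length(miss))
    stop_refstab("no efficiency for gene(s): %s", paste(miss, collapse = ", "))
  if (any(efficiencies <= 1))
    stop_refstab("efficiencies must be > 1 (E is the per-cycle amplification factor)")
  if (is.numeric(calibrator) && !is.null(names(calibrator))) {
    cal_cq <- calibrator
  } else {
    sel <- cq$species == calibrator$species &
           cq$tissue == calibrator$tissue &
           cq$bio_rep == calibrator$bio_rep
    cal_cq <- stats::setNames(cq$cq[sel], cq$gene[sel])
  }
  no_cal <- setdiff(unique(cq$gene), names(cal_cq))
  if (length(no_cal))
    stop_refstab("no calibrator Cq for gene(s): %s", paste(no_cal, collapse = ", "))
  e <- efficiencies[cq$gene]
  out <- cq
  out$rel_expr <- e ^ (cal_cq[cq$gene] - cq$cq)
  out
}

#' qPCR expression-stability CV
#'
#' Comparable to the RNA-seq CV: per gene, relative expression is first
#' averaged over biological replicates within each tissue, then the CV
#' (sample SD / mean) is taken across the tissue means. Because relative
#' expression enters both SD and mean, the CV is invariant to the choice of
#' calibrator (which rescales all of a gene's values by a constant).
#'
#' @param rel data.frame from [relative_expression] with columns `gene`,
#'   `tissue`, `bio_rep`, `rel_expr`.
#' @param exclude_tissues tissues to drop before the calculation (e.g.
#'   `"petal"` when one tissue is known to diverge).
#' @return data.frame with columns `gene`, `mean`, `sd`, `cv`, `n_tissues`.
#' @export
qpcr_cv <- function(rel, exclude_tissues = NULL) {
  need <- c("gene", "tissue", "rel_expr")
  miss <- setdiff(need, names(rel))
  if (length(miss))
    stop_refstab("relative-expression table lacks column(s): %s",
                 paste(miss, collapse = ", "))
  if (!is.null(exclude_tissues))
    rel <- rel[!(rel$tissue %in% exclude_tissues), , drop = FALSE]
  if (length(unique(rel$tissue)) < 2)
    stop_refstab("qpcr_cv needs at least 2 tissues after exclusion")
  rows <- lapply(split(rel, rel$gene), function(d) {
    tissue_means <- tapply(d$rel_expr, d$tissue, mean)
    tissue_means <- tissue_means[!is.na(tissue_means)]
    data.frame(gene = d$gene[1], mean = mean(tissue_means),
               sd = stats::sd(tissue_means), cv = cv_vec(tissue_means),
               n_tissues = length(tissue_means), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' 3'/5' cDNA integrity QC
#'
#' Compares expression estimates from assays at the 3' and 5' ends of the
#' same transcript on the same cDNA. A ratio far from 1 flags RNA degradation
#' or incomplete reverse transcription; the accepted range for qPCR use is
#' 0.2-5.0. The ratio is `E ^ (Cq_5p - Cq_3p)` (lower Cq = more template, so
#' a 5' assay lagging by k cycles means E^k-fold more 3' signal).
#'
#' @param cq_3p,cq_5p Cq values from the 3' and 5' assays (vectorized).
#' @param efficiency amplification efficiency E (default 2).
#' @param bounds acceptance interval (default `c(0.2, 5)`).
#' @return data.frame with columns `ratio_3p_5p` and `pass`.
#' @export
qc_3p5p <- function(cq_3p, cq_5p, efficiency = 2, bounds = c(0.2, 5)) {
  ratio <- efficiency ^ (cq_5p - cq_3p)
  data.frame(ratio_3p_5p = ratio,
             pass = ratio >= bounds[1] & ratio <= bounds[2])
}
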