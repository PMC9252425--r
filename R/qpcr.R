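# Relative qPCR quantification by the 2^-ddCt method with significance tiers.

#' Relative expression by the 2^-ddCt method
#'
#' For each (tissue, time point): technical replicates are averaged per
#' biological replicate; `dCt = Ct_gene - Ct_reference` per biological
#' replicate; `ddCt = mean(dCt_stressed) - mean(dCt_control)`; relative
#' expression is `2^-ddCt` (stressed vs control). Significance comes from a
#' two-sample Student's t test on the two dCt replicate sets (standard
#' Livak practice: the test is on dCt, not on folds), with tiers `*`, `**`,
#' `***` at p < 0.1, 0.05, 0.01. The fold-scale spread is the fold
#' equivalent of the ddCt standard error, `rel * (2^se - 1)`.
#'
#' A condition with no detected Ct (all NA) sets the status: stressed
#' detected but control undetected gives `not_quantifiable` (activation
#' from a silent baseline cannot be quantified), both undetected gives
#' `not_expressed`.
#'
#' @param table Ct data.frame with columns `gene`, `tissue`, `condition`
#'   (`control` / `stressed`), `time_h`, `bio_rep`, `tech_rep`, `ct`
#'   (NA = undetected).
#' @param gene Target gene id.
#' @param reference_gene Reference gene id (present in every block).
#' @param tiers P-value cut-offs for `*`, `**`, `***`
#'   (default `c(0.1, 0.05, 0.01)`).
#' @return data.frame, one row per (tissue, time_h): `gene`, `tissue`,
#'   `time_h`, `rel`, `sd`, `p_value`, `tier`, `status`, `n_bio_control`,
#'   `n_bio_stressed`.
#' @export
delta_delta_ct <- function(table, gene, reference_gene,
                           tiers = c(0.1, 0.05, 0.01)) {
  need <- c("gene", "tissue", "condition", "time_h", "bio_rep", "ct")
  stopifnot(all(need %in% names(table)))
  blocks <- unique(table[table$gene == gene, c("tissue", "time_h")])
  if (!nrow(blocks)) stop("gene not present in table: ", gene, call. = FALSE)

  res <- lapply(seq_len(nrow(blocks)), function(b) {
    tis <- blocks$tissue[b]; tm <- blocks$time_h[b]
    block <- table[table$tissue == tis & table$time_h == tm, ]
    dct <- lapply(c("control", "stressed"), function(cond) {
      sub <- block[block$condition == cond, ]
      g <- tech_means(sub[sub$gene == gene, ])
      r <- tech_means(sub[sub$gene == reference_gene, ])
      if (!length(r)) {
        stop("reference gene Cts missing for ", tis, " / ", cond,
             " / ", tm, "h", call. = FALSE)
      }
      reps <- intersect(names(g), names(r))
      g[reps] - r[reps]
    })
    names(dct) <- c("control", "stressed")
    ctrl <- dct$control[is.finite(dct$control)]
    strs <- dct$stressed[is.finite(dct$stressed)]

    status <- if (!length(ctrl) && !length(strs)) "not_expressed"
              else if (!length(ctrl)) "not_quantifiable"
              else "quantified"
    rel <- sd_fold <- p <- NA_real_
    tier <- "ns"
    if (status == "quantified" && length(strs)) {
      ddct <- mean(strs) - mean(ctrl)
      rel <- 2^(-ddct)
      if (length(ctrl) >= 2L && length(strs) >= 2L) {
        se <- sqrt(stats::var(strs) / length(strs) +
                     stats::var(ctrl) / length(ctrl))
        sd_fold <- rel * (2^se - 1)
        p <- if (stats::var(strs) < 1e-12 && stats::var(ctrl) < 1e-12) {
          # degenerate noise-free replicates: identical means are null
          if (abs(ddct) < 1e-12) 1 else 0
        } else {
          stats::t.test(strs, ctrl, var.equal = TRUE)$p.value
        }
        tier <- if (p < tiers[3]) "***"
                else if (p < tiers[2]) "**"
                else if (p < tiers[1]) "*"
                else "ns"
      } else {
        warning("fewer than 2 biological replicates in ", tis, " at ", tm,
                "h; p-value undefined", call. = FALSE)
      }
    }
    data.frame(gene = gene, tissue = tis, time_h = tm, rel = rel,
               sd = sd_fold, p_value = p, tier = tier, status = status,
               n_bio_control = length(ctrl), n_bio_stressed = length(strs),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# mean Ct over technical replicates, per biological replicate;
# a bio rep with no detected Ct at all comes back NaN
tech_means <- function(rows) {
  if (!nrow(rows)) return(stats::setNames(numeric(0), character(0)))
  out <- tapply(rows$ct, rows$bio_rep, function(x) {
    x <- x[!is.na(x)]
    if (!length(x)) NaN else mean(x)
  })
  stats::setNames(as.numeric(out), names(out))
}
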