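# Replicated qPCR Ct tables with known fold changes.

#' Simulate a replicated qPCR Ct table with planted fold changes
#'
#' Builds a Ct table in the standard layout (three biological replicates,
#' each with three technical replicates, stressed vs control per tissue and
#' time point) in which each target gene's stressed Ct is shifted by
#' `-log2(fold)` relative to control, while the reference gene's Ct is
#' constant in expectation across conditions — so that the downstream
#' 2^-ddCt quantification should recover the planted folds.
#'
#' @param true_fold_changes data.frame with columns `gene`, `tissue`,
#'   `time_h`, `fold` (fold > 0; fold = 1 is the null).
#' @param ct_noise_sd Standard deviation (cycles) of Gaussian noise added
#'   independently to every technical measurement.
#' @param n_bio,n_tech Numbers of biological and technical replicates
#'   (defaults 3 and 3).
#' @param seed Integer seed.
#' @param reference_gene Reference gene label (default `"RLIa"`, an RNase L
#'   inhibitor commonly used as internal reference in wheat qPCR).
#' @param ref_ct Mean reference-gene Ct (default 20).
#' @param target_ct Mean control-condition target Ct (default 26).
#' @return A list with `ct` (data.frame: `gene`, `tissue`, `condition`,
#'   `time_h`, `bio_rep`, `tech_rep`, `ct`) and `truth`
#'   (the input fold table).
#' @export
simulate_qpcr <- function(true_fold_changes,
                          ct_noise_sd = 0.1,
                          n_bio = 3L,
                          n_tech = 3L,
                          seed = 1L,
                          reference_gene = "RLIa",
                          ref_ct = 20,
                          target_ct = 26) {
  stopifnot(is.data.frame(true_fold_changes),
            all(c("gene", "tissue", "time_h", "fold") %in%
                  names(true_fold_changes)))
  if (any(true_fold_changes$fold <= 0)) {
    stop("all planted folds must be > 0", call. = FALSE)
  }
  n_bio <- check_count(n_bio, "n_bio", min = 1L)
  n_tech <- check_count(n_tech, "n_tech", min = 1L)

  with_seed(seed, {
    grid <- expand.grid(bio_rep = seq_len(n_bio), tech_rep = seq_len(n_tech),
                        condition = c("control", "stressed"),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    rows <- list()
    blocks <- unique(true_fold_changes[c("tissue", "time_h")])
    for (b in seq_len(nrow(blocks))) {
      tis <- blocks$tissue[b]; tm <- blocks$time_h[b]
      sub <- true_fold_changes[true_fold_changes$tissue == tis &
                                 true_fold_changes$time_h == tm, ]
      for (gene in c(reference_gene, sub$gene)) {
        is_ref <- gene == reference_gene
        shift <- if (is_ref) 0 else -log2(sub$fold[sub$gene == gene])
        base <- if (is_ref) ref_ct else target_ct
        # the reference gene is the stability-selected anchor: its Ct is
        # held constant; measurement noise enters through the targets
        noise <- if (is_ref) 0 else
          stats::rnorm(nrow(grid), sd = ct_noise_sd)
        ct <- base +
          ifelse(grid$condition == "stressed", shift, 0) + noise
        rows[[length(rows) + 1L]] <- data.frame(
          gene = gene, tissue = tis, condition = grid$condition,
          time_h = tm, bio_rep = grid$bio_rep, tech_rep = grid$tech_rep,
          ct = ct, stringsAsFactors = FALSE)
      }
    }
    ct_table <- do.call(rbind, rows)
    rownames(ct_table) <- NULL
    list(ct = ct_table, truth = true_fold_changes)
  })
}
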