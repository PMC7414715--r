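# Per-quartet score table for a family: every pair of paralog pairs gives
# one quartet with pattern counts, fate statistics and a duplication score.

#' Score all quartets of a family
#'
#' Enumerates every pair of paralog pairs and computes the pattern counts,
#' fate similarity (`F`, `Z_F`), asymmetry (`t`, `u`, `Z_A`) and duplication
#' score `D`.  Fate statistics use the untrimmed alignment; the duplication
#' score uses a gap-trimmed copy (likelihood route) or the trimmed pattern
#' counts (parsimony route), mirroring the use of trimmed alignments for
#' duplication inference and untrimmed ones for fates.
#'
#' @param aln A [family_alignment()].
#' @param pairs Paralog pairs from [extract_paralog_pairs()].
#' @param mode `"ml"` for ELW-based `D` (the reference route) or
#'   `"parsimony"` for the fast pattern-share screening `D`.
#' @param model Substitution model for the likelihood route.
#' @param B ELW resampling replicates.
#' @param seed Optional base seed; quartet `k` uses `seed + k`.
#' @param max_gap_frac Gap-fraction threshold for the trimmed duplication
#'   path (see [trim_gappy_columns()]).
#' @param estimate_shape Estimate the gamma shape per quartet.
#' @return Data frame with one row per quartet: `species_x`, `species_y`,
#'   `gene_a` .. `gene_d`, `l`, `n_Q`, `n_R`, `n_S`, `t`, `u`, `D`, `F`,
#'   `Z_F`, `Z_A`, `pairing`, `degenerate`.
#' @export
quartet_table <- function(aln, pairs, mode = c("ml", "parsimony"),
                          model = lg_model(), B = 1000L, seed = NULL,
                          max_gap_frac = 0.5, estimate_shape = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(aln, "family_alignment"), nrow(pairs) >= 2L)
  trimmed <- trim_gappy_columns(aln, max_gap_frac)$alignment
  coded <- encode_alignment(aln)
  coded_trim <- encode_alignment(trimmed)

  n <- nrow(pairs)
  idx <- utils::combn(n, 2L)
  rows <- vector("list", ncol(idx))
  for (k in seq_len(ncol(idx))) {
    i <- idx[1L, k]; j <- idx[2L, k]
    q <- quartet(pairs[i, ], pairs[j, ])
    cnt <- pattern_counts_coded(coded[q$a, ], coded[q$b, ],
                                coded[q$c, ], coded[q$d, ])
    if (cnt$degenerate) {
      fs <- list(F = NA_real_, Z_F = NA_real_, pairing = NA_character_)
      asy <- list(t = NA_integer_, u = NA_integer_, Z_A = NA_real_)
    } else {
      fs <- fate_similarity(cnt)
      asy <- asymmetry_scores(cnt, fs$pairing)
    }
    if (mode == "ml") {
      ml <- quartet_duplication_score(trimmed, q, model = model, B = B,
                                      seed = if (is.null(seed)) NULL else seed + k,
                                      estimate_shape = estimate_shape)
      D <- ml$D
    } else {
      tc <- pattern_counts_coded(coded_trim[q$a, ], coded_trim[q$b, ],
                                 coded_trim[q$c, ], coded_trim[q$d, ])
      D <- parsimony_weights(tc)$D
    }
    rows[[k]] <- data.frame(
      species_x = q$species_x, species_y = q$species_y,
      gene_a = q$a, gene_b = q$b, gene_c = q$c, gene_d = q$d,
      l = cnt$l, n_Q = cnt$n_Q, n_R = cnt$n_R, n_S = cnt$n_S,
      t = asy$t, u = asy$u, D = D, F = fs$F, Z_F = fs$Z_F, Z_A = asy$Z_A,
      pairing = fs$pairing, degenerate = cnt$degenerate,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
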