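# Junction expression index (JEI): for an annotated intron, the percent of
# junction reads supporting splicing of the exact intron among all reads
# supporting isoforms that use either its 5'ss or its 3'ss. 100% means fully
# canonical splicing of that intron; lower values indicate alternative paths
# such as cryptic-exon inclusion or alternative splice-site use.

#' Compute the JEI of one intron in one sample
#'
#' JEI = 100 x exact / denominator, where exact is the read count of the
#' donor->acceptor junction matching the intron precisely and the
#' denominator sums all junctions sharing the intron's donor OR acceptor
#' coordinate (the exact junction counted once). Junctions touching neither
#' splice site are excluded. `NA` when no read uses either splice site —
#' never silently zero.
#'
#' @param junctions Junction data.frame (see [read_junctions()]).
#' @param intron One row of [derive_introns()] output (or any list with
#'   contig, donor, acceptor).
#' @param sample Sample id.
#' @return Percent in \[0, 100\], or `NA_real_` when undefined.
#' @export
compute_jei <- function(junctions, intron, sample) {
  j <- junctions[junctions$sample_id == sample &
                 junctions$contig == intron$contig &
                 (junctions$donor == intron$donor |
                  junctions$acceptor == intron$acceptor), , drop = FALSE]
  denom <- sum(j$count)
  if (denom == 0) return(NA_real_)
  exact <- sum(j$count[j$donor == intron$donor & j$acceptor == intron$acceptor])
  100 * exact / denom
}

#' JEI of every intron in every sample
#'
#' @param junctions Junction data.frame.
#' @param introns Intron data.frame from [derive_introns()].
#' @param samples Sample ids; defaults to all samples present.
#' @return data.frame intron_id x sample matrix in long-friendly wide form:
#'   one row per intron, one `jei.<sample>` column per sample.
#' @export
jei_matrix <- function(junctions, introns, samples = unique(junctions$sample_id)) {
  m <- vapply(samples, function(s) {
    vapply(seq_len(nrow(introns)), function(i) {
      compute_jei(junctions, introns[i, ], s)
    }, numeric(1))
  }, numeric(nrow(introns)))
  m <- matrix(m, nrow = nrow(introns),
              dimnames = list(introns$intron_id, paste0("jei.", samples)))
  cbind(introns["intron_id"], as.data.frame(m))
}

#' Compare JEI between two sample groups for each intron
#'
#' Per intron, per-sample JEIs are averaged within group; percent reduction
#' is `100 * (1 - mean(treated) / mean(control))`; the group difference is
#' tested with a two-sided two-sample Student's t test (pooled variance by
#' default). An intron is flagged as a compound-induced splicing event when
#' reduction > `reduction_threshold` and P < `p_threshold`.
#'
#' Degenerate inputs: fewer than 2 defined JEIs in a group marks the intron
#' `untestable`; both groups constant and equal gives t = 0, P = 1; both
#' groups constant but unequal gives P = 0 with `degenerate = TRUE`.
#'
#' @param junctions Junction data.frame.
#' @param introns Intron data.frame.
#' @param manifest Sample manifest (sample_id, group, replicate).
#' @param control,treated Group labels.
#' @param reduction_threshold,p_threshold Flag thresholds (defaults 25, 0.05).
#' @param pooled_variance Use classical pooled-variance Student's t
#'   (default); `FALSE` for the unequal-variance form.
#' @return data.frame: intron_id, per-sample JEI columns, mean_control,
#'   mean_treated, reduction_pct, t, p, flagged, untestable, degenerate.
#' @export
compare_jei_groups <- function(junctions, introns, manifest,
                               control = "DMSO", treated = "treated",
                               reduction_threshold = 25, p_threshold = 0.05,
                               pooled_variance = TRUE) {
  sc <- manifest$sample_id[manifest$group == control]
  st <- manifest$sample_id[manifest$group == treated]
  if (!length(sc) || !length(st)) stop("empty group in manifest")
  jm <- jei_matrix(junctions, introns, samples = c(sc, st))
  res <- lapply(seq_len(nrow(introns)), function(i) {
    xc <- unlist(jm[i, paste0("jei.", sc)])
    xt <- unlist(jm[i, paste0("jei.", st)])
    xc <- xc[!is.na(xc)]; xt <- xt[!is.na(xt)]
    out <- data.frame(mean_control = NA_real_, mean_treated = NA_real_,
                      reduction_pct = NA_real_, t = NA_real_, p = NA_real_,
                      flagged = FALSE, untestable = FALSE, degenerate = FALSE)
    if (length(xc) < 2 || length(xt) < 2) {
      out$untestable <- TRUE
      return(out)
    }
    out$mean_control <- mean(xc)
    out$mean_treated <- mean(xt)
    out$reduction_pct <- 100 * (1 - out$mean_treated / out$mean_control)
    if (stats::var(xc) == 0 && stats::var(xt) == 0) {
      if (out$mean_control == out$mean_treated) {
        out$t <- 0; out$p <- 1
      } else {
        out$t <- Inf * sign(out$mean_control - out$mean_treated)
        out$p <- 0; out$degenerate <- TRUE
      }
    } else {
      tt <- stats::t.test(xc, xt, var.equal = pooled_variance)
      out$t <- unname(tt$statistic)
      out$p <- tt$p.value
    }
    out$flagged <- isTRUE(out$reduction_pct > reduction_threshold &&
                          out$p < p_threshold)
    out
  })
  cbind(jm, do.call(rbind, res))
}
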