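#' Estimate targeted copy number from depth ratios
#'
#' Ratio estimator for targeted panels: the copy number of the target
#' region is the control ploidy scaled by the ratio of mean per-base read
#' depth over the target to mean per-base depth over the pooled control
#' regions. `cn = ploidy_control * depth(target) / depth(controls)`. The
#' estimate is invariant to uniform depth rescaling of the whole dataset.
#' High-level amplification is flagged at `cn >= high_cn_threshold`
#' (inclusive; default 8, i.e. "eight or more" gene copies).
#'
#' @param reads alignment table.
#' @param target target region (`"chrom:start-end"` or list/row with
#'   chrom, start, end; 0-based half-open).
#' @param controls data.frame of control regions (columns chrom, start,
#'   end), disjoint from the target.
#' @param ploidy_control copies of the control regions in the genome
#'   (default 1: haploid chrX of a male genome).
#' @param high_cn_threshold copy-number threshold for the `high_cn` flag.
#' @return object of class `cn_estimate`: list with `region`,
#'   `mean_depth`, `control_depth`, `ploidy_control`, `cn`, `high_cn`.
#' @export
estimate_copy_number <- function(reads, target, controls, ploidy_control = 1,
                                 high_cn_threshold = 8) {
  target <- as_region(target)
  controls <- as.data.frame(controls)
  if (!nrow(controls)) stop("control regions must be non-empty")
  for (i in seq_len(nrow(controls))) {
    ctrl <- as_region(controls[i, ])
    if (ctrl$chrom == target$chrom &&
        ctrl$start < target$end && target$start < ctrl$end)
      stop("control region ", region_label(ctrl),
           " overlaps the target region")
  }
  dt <- as_reads_table(reads)
  depth_of <- function(region) {
    sub <- dt[chrom == region$chrom & pos < region$end & end > region$start]
    if (!nrow(sub)) return(0)
    sum(pmin(sub$end, region$end) - pmax(sub$pos, region$start)) /
      (region$end - region$start)
  }
  target_depth <- depth_of(target)
  ctrl_regions <- lapply(seq_len(nrow(controls)), function(i)
    as_region(controls[i, ]))
  ctrl_bases <- sum(vapply(ctrl_regions, function(r)
    depth_of(r) * (r$end - r$start), numeric(1L)))
  ctrl_width <- sum(vapply(ctrl_regions, function(r) r$end - r$start,
                           numeric(1L)))
  control_depth <- ctrl_bases / ctrl_width
  if (control_depth == 0) stop("control regions have zero read depth")
  cn <- ploidy_control * target_depth / control_depth
  structure(list(region = region_label(target), mean_depth = target_depth,
                 control_depth = control_depth,
                 ploidy_control = ploidy_control, cn = cn,
                 high_cn = flag_high_cn(cn, high_cn_threshold),
                 high_cn_threshold = high_cn_threshold),
            class = "cn_estimate")
}

#' @export
print.cn_estimate <- function(x, ...) {
  cat(sprintf(
    "Copy number of %s: %.2f (target depth %.1fx / control depth %.1fx, ploidy %g)\n",
    x$region, x$cn, x$mean_depth, x$control_depth, x$ploidy_control))
  cat(sprintf("  high-level amplification (cn >= %g): %s\n",
              x$high_cn_threshold, x$high_cn))
  invisible(x)
}

#' @export
as.data.frame.cn_estimate <- function(x, ...) {
  data.frame(region = x$region, mean_depth = x$mean_depth,
             control_depth = x$control_depth,
             ploidy_control = x$ploidy_control, cn = x$cn,
             high_cn = x$high_cn, stringsAsFactors = FALSE)
}

#' Flag high-level amplification
#'
#' Inclusive threshold: a copy number of exactly the threshold (default 8)
#' is flagged high ("eight or more" copies).
#'
#' @param cn numeric copy number estimate(s).
#' @param threshold copy-number threshold (default 8).
#' @return logical vector.
#' @examples
#' flag_high_cn(c(7.99, 8, 12))
#' @export
flag_high_cn <- function(cn, threshold = 8) {
  cn >= threshold
}
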