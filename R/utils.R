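## internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

## evaluate `expr` under a private RNG state seeded with `seed`,
## restoring the caller's state afterwards
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

## lowest value at which cumulative weight reaches half the total
## (ties resolved toward the lower coordinate)
weighted_median_low <- function(x, w) {
  stopifnot(length(x) == length(w), all(w > 0))
  o <- order(x)
  x <- x[o]; w <- w[o]
  x[which(cumsum(w) >= sum(w) / 2)[1L]]
}

## round half away from zero (base round() is half-to-even)
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## accept "chr:start-end" or a list/data.frame row with chrom/start/end
as_region <- function(region) {
  if (is.character(region) && length(region) == 1L) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1L]]
    if (length(m) != 4L)
      stop("cannot parse region string '", region, "' (expected chrom:start-end)")
    return(list(chrom = m[2L], start = as.numeric(m[3L]), end = as.numeric(m[4L])))
  }
  region <- as.list(region)
  if (!all(c("chrom", "start", "end") %in% names(region)))
    stop("region must have chrom, start and end")
  list(chrom = as.character(region$chrom[1L]),
       start = as.numeric(region$start[1L]),
       end = as.numeric(region$end[1L]))
}

region_label <- function(region) {
  sprintf("%s:%d-%d", region$chrom, as.integer(region$start),
          as.integer(region$end))
}

## standardise a reads table (data.frame or data.table) to a data.table
## with the alignment dialect columns; extra columns are kept
as_reads_table <- function(reads) {
  required <- c("read_id", "chrom", "pos", "end", "strand", "barcode")
  if (!is.data.frame(reads))
    stop("reads must be a data.frame")
  missing_cols <- setdiff(required, names(reads))
  if (length(missing_cols))
    stop("reads table lacks column(s): ", paste(missing_cols, collapse = ", "))
  dt <- as.data.table(reads)
  dt[, `:=`(chrom = as.character(chrom), pos = as.numeric(pos),
            end = as.numeric(end), barcode = as.character(barcode))]
  dt
}
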