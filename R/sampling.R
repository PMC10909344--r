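#' Draw one sampling bout with infection-state capture bias
#'
#' The expected number of infected captures is the infected proportion of the
#' population times the bias multiplier times the bout size, rounded to the
#' nearest integer and clamped to what the infected pool can supply.  That
#' many infected individuals, and enough uninfected individuals to fill the
#' bout, are drawn uniformly without replacement.  If one class cannot supply
#' its share the remainder is back-filled from the other class so the bout
#' size is always exact (this attenuates the realized bias; callers can see
#' it via the `clamped` attribute).
#'
#' @param pop Population data frame (any mixture of generations).
#' @param sample_size Bout size.
#' @param bias_value Positive capture-bias multiplier for infected hosts
#'   (1 = unbiased).
#' @return Integer vector of captured ids with attribute `clamped`
#'   (logical: was the infected target adjusted).
#' @export
draw_bout <- function(pop, sample_size, bias_value = 1) {
  n <- nrow(pop)
  if (sample_size > n)
    stop("sample_size exceeds population size", call. = FALSE)
  if (!is.finite(bias_value) || bias_value <= 0)
    stop("bias_value must be positive", call. = FALSE)
  inf_ids <- pop$id[pop$infected]
  uninf_ids <- pop$id[!pop$infected]
  prevalence <- length(inf_ids) / n
  k_target <- round(prevalence * bias_value * sample_size)
  k <- min(max(k_target, 0L), sample_size, length(inf_ids))
  n_uninf <- sample_size - k
  clamped <- k != k_target
  if (n_uninf > length(uninf_ids)) {
    shortfall <- n_uninf - length(uninf_ids)
    k <- k + shortfall
    n_uninf <- length(uninf_ids)
    clamped <- TRUE
  }
  ids <- c(
    if (k > 0) sample(inf_ids, k) else integer(0),
    if (n_uninf > 0) sample(uninf_ids, n_uninf) else integer(0)
  )
  attr(ids, "clamped") <- clamped
  ids
}

#' Build robust-design capture histories
#'
#' Runs `n_bouts` independent biased bouts over the pooled population and
#' records each individual's 0/1 detection vector.  Every individual is
#' retained, including never-detected ones (all-zero rows matter for the
#' sampled metrics; the CJS fit drops them itself).  Bouts do not
#' distinguish new captures from recaptures.
#'
#' @param pop Pooled population data frame (parents + offspring).
#' @param cfg A [scenario_config()].
#' @param bias_value Capture-bias multiplier applied to infected hosts in
#'   every bout (1 = control sampling).
#' @return A `capture_history` object: list with `detections` (n x n_bouts
#'   integer matrix), `individual_id`, `infected`, `genotype`, `generation`,
#'   `bias_value`, `clamped_bouts`.
#' @export
build_capture_histories <- function(pop, cfg, bias_value = 1) {
  stopifnot(inherits(cfg, "scenario_config"))
  det <- matrix(0L, nrow = nrow(pop), ncol = cfg$n_bouts)
  clamped_bouts <- 0L
  for (b in seq_len(cfg$n_bouts)) {
    ids <- draw_bout(pop, cfg$sample_size, bias_value)
    det[match(ids, pop$id), b] <- 1L
    if (isTRUE(attr(ids, "clamped"))) clamped_bouts <- clamped_bouts + 1L
  }
  structure(list(
    detections = det,
    individual_id = pop$id,
    infected = pop$infected,
    genotype = pop$genotype,
    generation = pop$generation,
    bias_value = bias_value,
    clamped_bouts = clamped_bouts
  ), class = "capture_history")
}

#' @export
print.capture_history <- function(x, ...) {
  nb <- ncol(x$detections)
  ever <- sum(rowSums(x$detections) > 0)
  cat(sprintf(
    "Capture histories: %d individuals, %d bouts, bias %.3g\n",
    nrow(x$detections), nb, x$bias_value))
  cat(sprintf("  detected at least once: %d; clamped bouts: %d\n",
              ever, x$clamped_bouts))
  invisible(x)
}

#' Ids of individuals detected in at least one bout
#'
#' @param ch A `capture_history`.
#' @return Integer vector of ids.
#' @export
detected_ids <- function(ch) {
  stopifnot(inherits(ch, "capture_history"))
  ch$individual_id[rowSums(ch$detections) > 0]
}

#' Write / read capture histories as delimited text
#'
#' Format: `id, generation, genotype, infected, bout_1 ... bout_T` — also the
#' input format of re-analysis mode.  The bias multiplier is a generation
#' artifact, not an observable, so it is stored as a `# bias_value:` comment
#' on write and recovered on read when present.
#'
#' @param ch A `capture_history`.
#' @param path File path.
#' @return The `capture_history` (read) or `path` invisibly (write).
#' @export
write_capture_histories <- function(ch, path) {
  stopifnot(inherits(ch, "capture_history"))
  df <- data.frame(id = ch$individual_id, generation = ch$generation,
                   genotype = ch$genotype, infected = ch$infected,
                   stringsAsFactors = FALSE)
  det <- as.data.frame(ch$detections)
  names(det) <- paste0("bout_", seq_len(ncol(det)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# bias_value: %.17g", ch$bias_value), con)
  utils::write.csv(cbind(df, det), con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_capture_histories
#' @export
read_capture_histories <- function(path) {
  first <- readLines(path, n = 1L)
  bias <- NA_real_
  if (startsWith(first, "# bias_value:"))
    bias <- as.numeric(sub("# bias_value:", "", first, fixed = TRUE))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  bout_cols <- grep("^bout_", names(df), value = TRUE)
  if (length(bout_cols) == 0)
    stop("no bout_* detection columns found in ", path, call. = FALSE)
  structure(list(
    detections = as.matrix(df[bout_cols]),
    individual_id = df$id,
    infected = as.logical(df$infected),
    genotype = df$genotype,
    generation = df$generation,
    bias_value = bias,
    clamped_bouts = NA_integer_
  ), class = "capture_history")
}
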