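#' Parameters of the differential secretion screen
#'
#' Defaults follow the screen the package implements: normalized 5'-end
#' counts are summed in sliding 5 bp windows (1 bp step), only windows
#' yielding at least 25 normalized reads are considered, candidate loci
#' must show a >= 1.5-fold secretome reduction in the mutant and
#' comparable-or-elevated intracellular levels.
#'
#' @param window Window width in bp (default 5).
#' @param step Step size in bp (default 1).
#' @param min_reads Normalized read floor applied to the larger of the two
#'   secretome window means (default 25).
#' @param fold Required wild-type/mutant secretome ratio (default 1.5).
#' @param intracellular_min_ratio Floor on mutant/wild-type intracellular
#'   ratio (default 1.0, i.e. parity).
#' @param intracellular_tolerance Subtracted from
#'   `intracellular_min_ratio` before comparison (default 0; the strictest
#'   reading of "comparable").
#' @return An object of class `screen_params`.
#' @export
screen_params <- function(window = 5L, step = 1L, min_reads = 25,
                          fold = 1.5, intracellular_min_ratio = 1.0,
                          intracellular_tolerance = 0) {
  stopifnot(window >= 1, step >= 1, min_reads > 0, fold > 1,
            intracellular_tolerance >= 0)
  structure(list(window = as.integer(window), step = as.integer(step),
                 min_reads = min_reads, fold = fold,
                 intracellular_min_ratio = intracellular_min_ratio,
                 intracellular_tolerance = intracellular_tolerance),
            class = "screen_params")
}

# wt/mut style ratio with the screen's division guard: x/0 -> +Inf for
# x > 0 (always passes a >= threshold), 0/0 -> 1 ("comparable").
safe_ratio <- function(num, den) {
  r <- num / den
  r[den == 0 & num > 0] <- Inf
  r[den == 0 & num == 0] <- 1
  r
}

#' Sliding-window sums of a 5'-end profile
#'
#' Each window `[s, s + window - 1]` holds the sum of per-position profile
#' values; windows truncated at the genome end are dropped.
#'
#' @param profile A normalized `five_prime_profile`.
#' @param p A [screen_params()] object.
#' @return An object of class `window_map`: list with `starts` (window
#'   start positions) and per-strand numeric vectors `plus`, `minus`
#'   aligned to `starts`.
#' @export
window_sums <- function(profile, p = screen_params()) {
  stopifnot(inherits(profile, "five_prime_profile"))
  if (!profile$normalized) {
    warning("profile is not normalized; window sums are on raw counts")
  }
  len <- length(profile$plus)
  if (len < p$window) stop("genome shorter than one window")
  starts <- seq.int(1L, len - p$window + 1L, by = p$step)
  roll <- function(v) {
    cs <- c(0, cumsum(v))
    (cs[starts + p$window] - cs[starts])
  }
  structure(list(starts = starts, plus = roll(profile$plus),
                 minus = roll(profile$minus), window = p$window),
            class = "window_map")
}

#' Mean of replicate window maps
#'
#' @param maps A list of two or more `window_map` objects sharing the same
#'   window keys.
#' @return A `window_map` of per-window arithmetic means.
#' @export
mean_windows <- function(maps) {
  if (!length(maps)) stop("no window maps given")
  ref <- maps[[1]]
  for (m in maps[-1]) {
    if (!identical(m$starts, ref$starts) || m$window != ref$window) {
      stop("window maps do not share the same keys")
    }
  }
  out <- ref
  out$plus <- Reduce(`+`, lapply(maps, `[[`, "plus")) / length(maps)
  out$minus <- Reduce(`+`, lapply(maps, `[[`, "minus")) / length(maps)
  out
}

#' Select candidate loci with condition-dependent secretion
#'
#' A window qualifies iff (i) the larger of the two secretome means reaches
#' `min_reads`, (ii) the wild-type/mutant secretome ratio is at least
#' `fold`, and (iii) the mutant/wild-type intracellular ratio is at least
#' `intracellular_min_ratio - intracellular_tolerance`. Runs of
#' overlapping qualifying windows on one strand merge into a single locus
#' whose borders are the union extent; the peak is the position of the
#' maximum per-position wild-type secretome value inside the locus
#' (leftmost on ties). Each strand is screened independently.
#'
#' @param wt_in,mut_in,wt_exo,mut_exo Mean `window_map`s of the four
#'   conditions (wild-type/mutant x intracellular/secretome), aligned.
#' @param p A [screen_params()] object.
#' @param wt_exo_profile Optional normalized `five_prime_profile` of the
#'   wild-type secretome used for peak pinpointing; without it the peak is
#'   the start of the qualifying window with the largest wild-type
#'   secretome sum.
#' @return A data frame of candidate loci: `strand`, `left`, `right`,
#'   `peak`, the four window means at the locus' best window (`wt_in`,
#'   `mut_in`, `wt_exo`, `mut_exo`), `exo_ratio` (wt/mut secretome) and
#'   `in_ratio` (mut/wt intracellular). Zero mutant denominators yield
#'   `Inf`.
#' @export
select_candidates <- function(wt_in, mut_in, wt_exo, mut_exo,
                              p = screen_params(), wt_exo_profile = NULL) {
  for (m in list(mut_in, wt_exo, mut_exo)) {
    if (!identical(m$starts, wt_in$starts)) stop("window maps not aligned")
  }
  out <- list()
  for (strand in c("+", "-")) {
    pick <- function(m) if (strand == "+") m$plus else m$minus
    v_wt_in <- pick(wt_in); v_mut_in <- pick(mut_in)
    v_wt_exo <- pick(wt_exo); v_mut_exo <- pick(mut_exo)
    exo_r <- safe_ratio(v_wt_exo, v_mut_exo)
    in_r <- safe_ratio(v_mut_in, v_wt_in)
    ok <- pmax(v_wt_exo, v_mut_exo) >= p$min_reads &
      exo_r >= p$fold &
      in_r >= p$intracellular_min_ratio - p$intracellular_tolerance
    idx <- which(ok)
    if (!length(idx)) next
    s <- wt_in$starts[idx]
    grp <- cumsum(c(TRUE, diff(s) > wt_in$window - 1L))
    for (g in split(seq_along(idx), grp)) {
      ii <- idx[g]
      left <- wt_in$starts[ii[1]]
      right <- wt_in$starts[ii[length(ii)]] + wt_in$window - 1L
      best <- ii[which.max(v_wt_exo[ii])]
      peak <- if (!is.null(wt_exo_profile)) {
        v <- if (strand == "+") wt_exo_profile$plus else wt_exo_profile$minus
        (left:right)[which.max(v[left:right])]
      } else {
        wt_in$starts[best]
      }
      out[[length(out) + 1L]] <- data.frame(
        strand = strand, left = left, right = right, peak = peak,
        wt_in = v_wt_in[best], mut_in = v_mut_in[best],
        wt_exo = v_wt_exo[best], mut_exo = v_mut_exo[best],
        exo_ratio = exo_r[best], in_ratio = in_r[best])
    }
  }
  if (!length(out)) {
    return(data.frame(strand = character(), left = integer(),
                      right = integer(), peak = integer(),
                      wt_in = numeric(), mut_in = numeric(),
                      wt_exo = numeric(), mut_exo = numeric(),
                      exo_ratio = numeric(), in_ratio = numeric()))
  }
  res <- do.call(rbind, out)
  res[order(res$strand, res$left), , drop = FALSE]
}

#' Differential secretion screen over replicate profiles
#'
#' Convenience wrapper: windows each replicate profile, averages replicates
#' per condition, and selects candidate loci.
#'
#' @param wt_in,mut_in,wt_exo,mut_exo Lists of replicate
#'   `five_prime_profile`s for the four conditions.
#' @param p A [screen_params()] object.
#' @return As [select_candidates()].
#' @export
differential_screen <- function(wt_in, mut_in, wt_exo, mut_exo,
                                p = screen_params()) {
  mw <- function(profiles) mean_windows(lapply(profiles, window_sums, p = p))
  mean_prof <- function(profiles) {
    out <- profiles[[1]]
    out$plus <- Reduce(`+`, lapply(profiles, `[[`, "plus")) / length(profiles)
    out$minus <- Reduce(`+`, lapply(profiles, `[[`, "minus")) / length(profiles)
    out
  }
  select_candidates(mw(wt_in), mw(mut_in), mw(wt_exo), mw(mut_exo), p,
                    wt_exo_profile = mean_prof(wt_exo))
}
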