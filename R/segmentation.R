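# Deterministic segmentation of a conversation's help-seeker messages.
# Only help-seeker messages are counted: supporter text is never analyzed,
# so segment boundaries are defined on the analyzed stream.

# round half up; R's round() rounds half to even
.rhu <- function(x) floor(x + 0.5)

#' Split a conversation into three equal phases
#'
#' Partitions the half-open range `[0, n)` of help-seeker message ordinals
#' into beginning, middle and end phases of as-equal-as-possible size.
#' Remainder messages are assigned to the earliest phases: `n = 3q + 1`
#' gives sizes `q+1, q, q` and `n = 3q + 2` gives `q+1, q+1, q`.
#'
#' @param n number of help-seeker messages (must be at least 3).
#' @return data frame with columns `label` (beginning/middle/end),
#'   `start`, `end` (half-open index spans).
#' @examples
#' split_phases(12)  # spans [0,4), [4,8), [8,12)
#' split_phases(10)  # sizes 4, 3, 3
#' @export
split_phases <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 3L) {
    stop("cannot split a conversation of ", n, " messages into thirds ",
         "(need n >= 3)")
  }
  q <- n %/% 3L
  r <- n %% 3L
  sizes <- q + as.integer(seq_len(3L) <= r)
  ends <- cumsum(sizes)
  data.frame(label = c("beginning", "middle", "end"),
             start = c(0L, ends[1L], ends[2L]),
             end = ends,
             stringsAsFactors = FALSE)
}

#' Nine overlapping 20%-width windows over a conversation
#'
#' Window `k` (ordinals 1-9) spans message indices
#' `[round(0.1 (k-1) n), round(0.1 (k-1) n + 0.2 n))` with round-half-up,
#' i.e. a 20% window size stepped by 10% so each window starts at the
#' midpoint of the previous one. The last window always ends at `n`.
#'
#' @param n number of help-seeker messages (must be at least 10, the
#'   eligibility floor, so that all nine windows are nonempty).
#' @return data frame with columns `ordinal` (1-9), `start`, `end`
#'   (half-open index spans).
#' @examples
#' make_windows(20)  # widths all 4, starts 0, 2, ..., 16
#' @export
make_windows <- function(n) {
  n <- as.integer(n)
  if (is.na(n) || n < 10L) {
    stop("cannot form 9 overlapping windows for n = ", n,
         " messages (need n >= 10)")
  }
  k <- 0:8
  s <- as.integer(pmax(0, pmin(.rhu(k * n / 10), n)))
  e <- as.integer(pmax(0, pmin(.rhu((k + 2) * n / 10), n)))
  e[9L] <- n
  data.frame(ordinal = 1:9, start = s, end = e)
}
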