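#' Coerce to a survival group
#'
#' A survival group is a two-column structure of observed times and event
#' indicators (1 = event, 0 = censored). Accepts a data.frame or matrix with
#' columns `time` and `event` (or the first two columns), or a list with
#' those elements.
#'
#' @param x Object to coerce.
#' @return data.frame with numeric `time` and integer `event`.
#' @export
as_survival_group <- function(x) {
  if (is.list(x) && !is.data.frame(x) && all(c("time", "event") %in% names(x))) {
    x <- data.frame(time = x$time, event = x$event)
  }
  if (is.matrix(x)) x <- as.data.frame(x)
  stopifnot(is.data.frame(x))
  if (!all(c("time", "event") %in% colnames(x))) {
    colnames(x)[1:2] <- c("time", "event")
  }
  out <- data.frame(time = as.numeric(x$time), event = as.integer(x$event))
  if (nrow(out) && (any(!is.finite(out$time)) || any(out$time <= 0) ||
                    any(!out$event %in% c(0L, 1L)))) {
    ipp_stop("survival group needs positive finite times and 0/1 events",
             "invalid_survival_group")
  }
  out
}

#' Signed two-group log-rank z-score
#'
#' Standard (unweighted) log-rank comparison of the `high` and `low` groups,
#' reported as a signed z-score. Over the pooled distinct event times t with
#' d_t total events, n_t patients at risk and n_Ht of them in the high
#' group, the observed and expected high-group events are O_H = sum of
#' high-group events and E_H = sum d_t * n_Ht / n_t, with hypergeometric
#' variance V = sum d_t (n_Ht/n_t)(1 - n_Ht/n_t)(n_t - d_t)/(n_t - 1) (the
#' tie factor is dropped when n_t = 1). The score is
#' \deqn{z = -(O_H - E_H)/\sqrt{V},}
#' so a *negative* z means the high group experienced more events than
#' expected, i.e. high values mark higher risk. Degenerate comparisons with
#' V = 0 (no events, or a risk set that never mixes the groups) return z = 0.
#'
#' Patients censored at an event time are kept in that time's risk set
#' (events are processed before censoring at ties). Internally O_H - E_H is
#' accumulated as sum (d_Ht n_Lt - d_Lt n_Ht)/n_t and the variance through
#' the symmetric product n_Ht n_Lt, so swapping the two group labels negates
#' z *exactly* (to the last bit), not merely up to rounding.
#'
#' @param high,low Survival groups (see [as_survival_group()]).
#' @return Object of class `"logrank_result"`: list with `z`,
#'   `observed_high`, `expected_high`, `variance`, `degenerate`.
#' @examples
#' high <- data.frame(time = c(1, 2), event = c(1, 1))
#' low <- data.frame(time = c(3, 4), event = c(1, 1))
#' logrank_z(high, low)$z # negative: high group fails first
#' @export
logrank_z <- function(high, low) {
  h <- as_survival_group(high)
  l <- as_survival_group(low)
  if (nrow(h) == 0L || nrow(l) == 0L) {
    ipp_stop("both survival groups must be non-empty", "empty_group")
  }
  time <- c(h$time, l$time)
  event <- c(h$event, l$event)
  in_high <- rep(c(TRUE, FALSE), c(nrow(h), nrow(l)))

  ut <- sort(unique(time[event == 1L]))
  O_H <- sum(h$event)
  E_H <- 0
  U <- 0 # O_H - E_H accumulated in a form exactly antisymmetric in the labels
  V <- 0
  for (t in ut) {
    at_risk <- time >= t
    n_t <- sum(at_risk)
    n_Ht <- sum(at_risk & in_high)
    n_Lt <- n_t - n_Ht
    is_d <- time == t & event == 1L
    d_t <- sum(is_d)
    d_Ht <- sum(is_d & in_high)
    d_Lt <- d_t - d_Ht
    E_H <- E_H + d_t * n_Ht / n_t
    U <- U + (d_Ht * n_Lt - d_Lt * n_Ht) / n_t
    if (n_t > 1L) {
      V <- V + d_t * (n_Ht * n_Lt) * (n_t - d_t) / (n_t * n_t) / (n_t - 1)
    }
  }
  degenerate <- V <= 0
  z <- if (degenerate) 0 else -U / sqrt(V)
  structure(list(z = z, observed_high = O_H, expected_high = E_H,
                 variance = V, degenerate = degenerate),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank: z = %.4f (O_high = %g, E_high = %.4f, V = %.4f)%s\n",
              x$z, x$observed_high, x$expected_high, x$variance,
              if (x$degenerate) " [degenerate]" else ""))
  invisible(x)
}

#' P-value for a signed log-rank z-score
#'
#' @param result A `"logrank_result"` (or a bare numeric z).
#' @param sidedness `"two"` (default) or `"one"`.
#' @param direction For one-sided tests, the alternative: `"negative"`
#'   (high group at higher risk, i.e. small p when z is very negative) or
#'   `"positive"`. Required when `sidedness = "one"`.
#' @return Numeric p-value.
#' @examples
#' logrank_p(list(z = 1.96), sidedness = "two") # ~0.05
#' @export
logrank_p <- function(result, sidedness = c("two", "one"), direction = NULL) {
  sidedness <- match.arg(sidedness)
  z <- if (is.numeric(result)) result[[1L]] else result$z
  stopifnot(is.finite(z))
  if (sidedness == "two") {
    return(2 * pnorm(-abs(z)))
  }
  if (is.null(direction)) {
    ipp_stop("one-sided log-rank p-value needs a direction ('negative' or 'positive')",
             "missing_direction")
  }
  direction <- match.arg(direction, c("negative", "positive"))
  s <- if (direction == "negative") 1 else -1
  pnorm(z * s)
}
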