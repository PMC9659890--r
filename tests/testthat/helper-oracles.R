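# Independent brute-force oracles used to cross-check the implementation.
# These deliberately take the slow, enumerative route.

# %DwT as 100 * (window days not covered by the union of 30-day supply
# intervals) / window, computed day by day.
brute_dwt <- function(dates, window_days = 360) {
  d <- as.numeric(dates) - as.numeric(dates)[1]
  d <- d[d < window_days]
  covered <- unique(unlist(lapply(d, function(x) seq(x, x + 29))))
  covered <- covered[covered < window_days]
  100 * (window_days - length(covered)) / window_days
}

# Episode starts by enumerating every run of three consecutive calendar
# months between the first and last dispensing.
brute_triples <- function(dates) {
  if (length(dates) == 0) return(as.Date(character()))
  dates <- sort(dates)
  firsts <- as.Date(paste0(format(dates, "%Y-%m"), "-01"))
  months <- seq(min(firsts), max(firsts), by = "1 month")
  present <- months %in% firsts
  starts <- as.Date(character())
  if (length(months) >= 3) {
    for (i in seq_len(length(months) - 2)) {
      if (all(present[i:(i + 2)])) {
        starts <- c(starts, min(dates[firsts == months[i]]))
      }
    }
  }
  starts
}

# PAP choice by total-order scoring: demoted class, then longest span,
# then earliest first date, then name.
brute_pap <- function(qualifying, registry = ap_registry()) {
  q <- qualifying
  q$span <- as.numeric(q$last_date - q$first_date)
  q$demoted <- is_excluded_from_pap_priority(q$molecule, registry)
  q[order(q$demoted, -q$span, q$first_date, q$molecule), ][1, ]$molecule
}

# Quantile by explicit linear interpolation between order statistics.
brute_quantile <- function(x, p) {
  x <- sort(x)
  n <- length(x)
  h <- (n - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  x[lo] + (h - lo) * (x[hi] - x[lo])
}

# Covered day set of a patient's coverage spells (closed intervals).
brute_day_set <- function(spells) {
  if (nrow(spells) == 0) return(numeric(0))
  sort(unique(unlist(Map(
    seq, as.numeric(spells$start_date), as.numeric(spells$end_date)
  ))))
}

# Random sorted in-window dispensing date sets for property tests.
random_date_set <- function(n_max = 12, window_days = 360) {
  n <- sample(1:n_max, 1)
  origin <- as.Date("2010-01-01") + sample(0:2000, 1)
  offsets <- sort(c(0, sample(1:(window_days + 60), n - 1, replace = TRUE)))
  origin + unique(offsets)
}

# Minimal claims object from component tibbles (defaults empty).
make_claims <- function(patients = NULL, ald = NULL, coverage = NULL,
                        dispensings = NULL, diagnoses = NULL) {
  empty_date <- as.Date(character())
  apclaims:::new_claims(
    patients = patients %||% tibble::tibble(
      patient_id = character(), birth_year = integer(),
      birth_month = integer(), sex = character(), death_date = empty_date,
      free_access = logical()
    ),
    ald = ald %||% tibble::tibble(
      patient_id = character(), code = character(), start_date = empty_date
    ),
    coverage = coverage %||% tibble::tibble(
      patient_id = character(), start_date = empty_date, end_date = empty_date
    ),
    dispensings = dispensings %||% tibble::tibble(
      patient_id = character(), date = empty_date, molecule = character(),
      form = character(), units = integer(), mg_per_unit = double(),
      prescriber_specialty = character()
    ),
    diagnoses = diagnoses %||% tibble::tibble(
      patient_id = character(), date = empty_date, icd10_code = character()
    )
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

simple_dispensing <- function(pid, dates, molecule, units = 30L, mg = 2,
                              specialty = "general_practitioner",
                              form = "oral") {
  tibble::tibble(
    patient_id = pid, date = dates, molecule = molecule, form = form,
    units = as.integer(units), mg_per_unit = mg,
    prescriber_specialty = specialty
  )
}

# Exact expected %DwT for the renewal refill process with integer delay pmf
# `p` (support 0..length(p)-1) and dispensings continuing past the window:
# dynamic programme over the remaining window length.
uncovered_dp <- function(p, window_days = 360) {
  k <- seq_along(p) - 1
  E <- numeric(window_days + 1) # E[w+1] = expected uncovered days in window w
  for (w in 31:window_days) {
    rest <- w - 30 - k
    E[w + 1] <- sum(p * (pmin(k, w - 30) + E[ifelse(rest > 0, rest, 0) + 1]))
  }
  E
}

expected_dwt <- function(p, window_days = 360) {
  100 * uncovered_dp(p, window_days)[window_days + 1] / window_days
}

# Exact E[%DwT | inclusion] for a refill stream anchored at t0, conditioned on
# the three-consecutive-calendar-month inclusion rule: the two calendar months
# after the anchor's month must each receive a dispensing. Walks dispensing
# offsets with states "both months still needed" / "second month needed",
# accumulating delay days (= uncovered days inside the window) on surviving
# paths, then appends the unconditional remainder.
conditional_dwt_one <- function(p, t0, Euncond, window_days = 360) {
  k <- seq_along(p) - 1
  m0_end <- lubridate::ceiling_date(t0, "month") - 1
  m1_end <- lubridate::ceiling_date(m0_end + 1, "month") - 1
  m2_end <- lubridate::ceiling_date(m1_end + 1, "month") - 1
  e0 <- as.numeric(m0_end - t0)
  e1 <- as.numeric(m1_end - t0)
  e2 <- as.numeric(m2_end - t0)
  cls <- function(o) {
    ifelse(o <= e0, 0L, ifelse(o <= e1, 1L, ifelse(o <= e2, 2L, 3L)))
  }
  P <- matrix(0, e2 + 1, 2)
  V <- matrix(0, e2 + 1, 2)
  for (o in e2:0) {
    op <- o + 30 + k
    c_next <- cls(op)
    # state 2: only the second month still needed; success on entering it
    succ <- c_next == 2L
    stay <- c_next <= 1L
    ps <- numeric(length(k))
    vs <- numeric(length(k))
    ps[succ] <- 1
    vs[succ] <- k[succ] + Euncond[window_days - op[succ] + 1]
    if (any(stay)) {
      ps[stay] <- P[op[stay] + 1, 2]
      vs[stay] <- k[stay] * P[op[stay] + 1, 2] + V[op[stay] + 1, 2]
    }
    P[o + 1, 2] <- sum(p * ps)
    V[o + 1, 2] <- sum(p * vs)
    # state 1: both months needed; entering the first month moves to state 2,
    # overshooting it fails the inclusion condition
    to_m2 <- c_next == 1L
    stay0 <- c_next == 0L
    ps <- numeric(length(k))
    vs <- numeric(length(k))
    if (any(to_m2)) {
      ps[to_m2] <- P[op[to_m2] + 1, 2]
      vs[to_m2] <- k[to_m2] * P[op[to_m2] + 1, 2] + V[op[to_m2] + 1, 2]
    }
    if (any(stay0)) {
      ps[stay0] <- P[op[stay0] + 1, 1]
      vs[stay0] <- k[stay0] * P[op[stay0] + 1, 1] + V[op[stay0] + 1, 1]
    }
    P[o + 1, 1] <- sum(p * ps)
    V[o + 1, 1] <- sum(p * vs)
  }
  100 / window_days * V[1, 1] / P[1, 1]
}

# Patient-weighted conditional expectation over realized inclusion dates.
conditional_dwt <- function(p, anchors, window_days = 360) {
  Eu <- uncovered_dp(p, window_days)
  key <- paste(
    lubridate::mday(anchors), lubridate::month(anchors),
    lubridate::leap_year(anchors)
  )
  vals <- vapply(split(seq_along(anchors), key), function(idx) {
    conditional_dwt_one(p, anchors[idx[1]], Eu, window_days)
  }, numeric(1))
  mean(vals[key])
}
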