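#' Build the odor/contingency scheme for a conditioning paradigm
#'
#' Defines the six-odor panel and its reward contingencies. Three odors are
#' ketones (hexanone, heptanone, octanone) and three are terpenes (terpinene,
#' pinene, limonene); contingencies are balanced so that chemical class never
#' predicts outcome.
#'
#' In the switch paradigm (`"exp1"`) each contingency group -- sucrose (`S`),
#' control (`X`), airpuff (`P`) -- contains exactly one ketone and one
#' terpene. From the switch day (day 4) onward every odor carries a
#' reassigned contingency. In the lick-spout paradigm (`"exp2"`) the odors
#' split into a spout-present group (`L`) and a spout-removed group (`N`),
#' and each sucrose probability (0, 0.5, 1) occurs exactly once per group.
#'
#' @param paradigm `"exp1"` (contingency-switch conditioning) or `"exp2"`
#'   (lick-spout removal with probabilistic sucrose).
#' @param day Imaging day, 1-6 for `"exp1"`; ignored for `"exp2"`.
#' @param seed Unused for the fixed default assignment; accepted so callers
#'   can treat every generator uniformly.
#' @return A tibble of class `odor_scheme` with one row per odor and columns
#'   `odor`, `chem_class`, and either `contingency` (`S`/`X`/`P`, exp1) or
#'   `spout` (`L`/`N`), `p_sucrose` and `role` (exp2). Attributes carry
#'   `paradigm`, `day`, and `switch_day`.
#' @export
#' @examples
#' make_odor_scheme("exp1", day = 2)
#' make_odor_scheme("exp2")
make_odor_scheme <- function(paradigm = c("exp1", "exp2"), day = 1L, seed = NULL) {
  paradigm <- match.arg(paradigm)
  odors <- c("hexanone", "heptanone", "octanone", "terpinene", "pinene", "limonene")
  chem <- c("ketone", "ketone", "ketone", "terpene", "terpene", "terpene")
  switch_day <- 4L

  if (paradigm == "exp1") {
    if (!is.numeric(day) || day < 1 || day > 6) {
      abort("`day` must be in 1..6 for the switch paradigm")
    }
    contingency <- if (day < switch_day) {
      # days 1-3: heptanone/pinene -> sucrose, octanone/limonene -> airpuff
      c(hexanone = "X", heptanone = "S", octanone = "P",
        terpinene = "X", pinene = "S", limonene = "P")
    } else {
      # days 4-6: every odor reassigned
      c(hexanone = "P", heptanone = "X", octanone = "S",
        terpinene = "S", pinene = "P", limonene = "X")
    }
    out <- tibble(
      odor = odors, chem_class = chem,
      contingency = unname(contingency[odors])
    )
    out$role <- paste0(out$contingency, "_",
                       ifelse(out$chem_class == "ketone", "K", "T"))
  } else {
    # L = spout stays, N = spout retracted; one odor per sucrose
    # probability within each spout group.
    out <- tibble(
      odor = odors, chem_class = chem,
      spout = c("L", "L", "N", "N", "L", "N"),
      p_sucrose = c(0, 0.5, 1, 0, 1, 0.5)
    )
    lab <- ifelse(out$p_sucrose == 1, "hi", ifelse(out$p_sucrose == 0.5, "lo", "X"))
    out$role <- paste0(out$spout, "_", lab)
  }
  structure(out,
    class = c("odor_scheme", class(out)),
    paradigm = paradigm, day = as.integer(day), switch_day = switch_day
  )
}

#' Contingency value of each odor under a scheme
#'
#' Maps odors to the scalar "value" regressor used by the encoding model:
#' for the switch paradigm, 1 for sucrose-contingent odors and 0 otherwise
#' (optionally -1 for airpuff odors); for the lick-spout paradigm, the
#' sucrose probability.
#'
#' @param scheme An [make_odor_scheme()] scheme.
#' @param signed If `TRUE` (exp1 only) airpuff odors get value -1.
#' @return Named numeric vector over the six odors.
#' @export
odor_value <- function(scheme, signed = FALSE) {
  if (attr(scheme, "paradigm") == "exp1") {
    v <- ifelse(scheme$contingency == "S", 1, 0)
    if (signed) v[scheme$contingency == "P"] <- -1
  } else {
    v <- scheme$p_sucrose
  }
  setNames(v, scheme$odor)
}

#' Pseudorandomized block design of conditioning trials
#'
#' Trials are organized into blocks; each block presents each of the six
#' odors once in randomized order, with the constraint that the same odor is
#' never presented more than twice in a row (enforced across block
#' boundaries). Outcome timing follows the paradigm: a 2 s odor, a variable
#' trace delay (0.1-0.3 s for the switch paradigm, 1.1-1.3 s for the
#' lick-spout paradigm), and a 12-18 s intertrial interval. In the
#' lick-spout paradigm sucrose delivery is realized per trial as a Bernoulli
#' draw at the odor's sucrose probability, and `spout_present` records
#' whether the spout stays within reach.
#'
#' @param scheme An [make_odor_scheme()] scheme.
#' @param n_blocks Number of blocks (30 in a standard session).
#' @param seed Integer seed.
#' @param lead_in_s Seconds of plain baseline recording before the first
#'   trial (gives the pre-odor window of trial 1 room to exist).
#' @return A tibble of class `trial_table`: `trial_index`, `block`, `odor`,
#'   `odor_on`, `odor_off`, `us_type`, `us_time`, `spout_present`, `iti`
#'   (all times in seconds from session start).
#' @export
#' @examples
#' trials <- build_trial_table(make_odor_scheme("exp1", 2), n_blocks = 2, seed = 1)
#' table(trials$odor)
build_trial_table <- function(scheme, n_blocks = 30L, seed = NULL, lead_in_s = 10) {
  stopifnot(inherits(scheme, "odor_scheme"), n_blocks >= 1)
  if (!is.null(seed)) set.seed(seed)
  paradigm <- attr(scheme, "paradigm")
  odors <- scheme$odor

  seq_odors <- character(0)
  for (b in seq_len(n_blocks)) {
    repeat {
      perm <- sample(odors)
      cand <- c(tail(seq_odors, 2), perm)
      runs <- rle(cand)$lengths
      if (max(runs) <= 2) {
        seq_odors <- c(seq_odors, perm)
        break
      }
    }
  }

  n <- length(seq_odors)
  delay <- if (paradigm == "exp1") runif(n, 0.1, 0.3) else runif(n, 1.1, 1.3)
  iti <- runif(n, 12, 18)

  if (paradigm == "exp1") {
    cont <- setNames(scheme$contingency, scheme$odor)[seq_odors]
    us_type <- c(S = "sucrose", P = "airpuff", X = "none")[cont]
    spout <- rep(TRUE, n)
  } else {
    ps <- setNames(scheme$p_sucrose, scheme$odor)[seq_odors]
    us_type <- ifelse(rbinom(n, 1, ps) == 1, "sucrose", "none")
    spout <- setNames(scheme$spout, scheme$odor)[seq_odors] == "L"
  }

  odor_on <- numeric(n)
  t <- lead_in_s
  for (i in seq_len(n)) {
    odor_on[i] <- t
    t <- t + 2 + delay[i] + iti[i]
  }

  out <- tibble(
    trial_index = seq_len(n),
    block = rep(seq_len(n_blocks), each = 6),
    odor = seq_odors,
    odor_on = odor_on,
    odor_off = odor_on + 2,
    us_type = unname(us_type),
    us_time = odor_on + 2 + delay,
    spout_present = unname(spout),
    iti = iti
  )
  structure(out,
    class = c("trial_table", class(out)),
    paradigm = paradigm, scheme = scheme
  )
}
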