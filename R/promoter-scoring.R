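# Promoter scoring: exponential score weighting and a self-contained
# sigma70 consensus-PWM scanner used when no external predictor table is
# available.

#' Promoter score weighting scheme
#'
#' Raw predictor scores are probability-like values in `[0, 1]`; to make a
#' region's cumulative score favour a few strong promoters over many weak
#' ones, each score is exponentially weighted before summation:
#' `w(s) = exp(s)`. The weight is strictly increasing and convex on `[0, 1]`
#' with `w(0) = 1`, so a single maximal-score promoter contributes
#' `e = 2.718...` while a borderline one contributes just above `e^0.5`.
#'
#' @param kind Currently only `"exponential"`.
#' @return A `weighting_scheme` object with elements `kind` and `weight`
#'   (the weight function).
#' @export
weighting_scheme <- function(kind = c("exponential")) {
  kind <- match.arg(kind)
  structure(list(kind = kind, weight = exp), class = "weighting_scheme")
}

#' Apply the score weighting
#'
#' @param s Numeric vector of raw prediction scores in `[0, 1]`.
#' @param scheme A [weighting_scheme()].
#' @return The weighted scores `exp(s)`.
#' @export
weight_score <- function(s, scheme = weighting_scheme()) {
  stopifnot(inherits(scheme, "weighting_scheme"))
  if (any(is.na(s)) || any(s < 0 | s > 1))
    stop("scores must lie in [0, 1]")
  scheme$weight(s)
}

#' Built-in sigma70 promoter model
#'
#' A two-box position-weight-matrix model of the bacterial sigma70 promoter:
#' a -35 box (consensus `TTGACA`) and a -10 box (consensus `TATAAT`)
#' separated by a spacer of 15-21 bp. Each matrix column holds base
#' probabilities summing to 1 (`match_prob` on the consensus base, the
#' remainder split evenly); scanning scores are summed log-odds against a
#' uniform background, mapped to `[0, 1]` through a logistic so they are
#' commensurate with the probability-like scores of external predictors. The
#' default calibration (`score_midpoint = 7`, `score_scale = 1.1`) puts the
#' exact consensus above 0.999 and typical random sequence below 0.1.
#'
#' @param minus35,minus10 4 x width probability matrices (rows A,C,G,T).
#' @param spacer_range Integer `c(min, max)` allowed spacer lengths in bp.
#' @param score_midpoint,score_scale Logistic calibration mapping summed
#'   log-odds `x` to `1 / (1 + exp(-(x - midpoint) / scale))`.
#' @param background Base composition assumed for the log-odds (length 4,
#'   sums to 1).
#' @return A `pwm_model` object.
#' @export
pwm_model <- function(minus35 = consensus_pwm("TTGACA"),
                      minus10 = consensus_pwm("TATAAT"),
                      spacer_range = c(15L, 21L),
                      score_midpoint = 7,
                      score_scale = 1.1,
                      background = rep(0.25, 4)) {
  stopifnot(nrow(minus35) == 4L, nrow(minus10) == 4L,
            length(spacer_range) == 2L, spacer_range[1] <= spacer_range[2],
            length(background) == 4L, abs(sum(background) - 1) < 1e-6)
  if (any(abs(colSums(minus35) - 1) > 1e-6) ||
      any(abs(colSums(minus10) - 1) > 1e-6))
    stop("PWM columns must sum to 1")
  structure(list(minus35 = minus35, minus10 = minus10,
                 spacer_range = as.integer(spacer_range),
                 score_midpoint = score_midpoint, score_scale = score_scale,
                 background = background),
            class = "pwm_model")
}

#' Build a probability matrix from a consensus sequence
#'
#' @param consensus DNA string.
#' @param match_prob Probability assigned to the consensus base in each
#'   column (default 0.85); the rest is split evenly.
#' @return A 4 x nchar(consensus) matrix with rows A, C, G, T.
#' @export
consensus_pwm <- function(consensus, match_prob = 0.85) {
  bases <- c("A", "C", "G", "T")
  cc <- strsplit(toupper(consensus), "")[[1]]
  stopifnot(all(cc %in% bases))
  m <- matrix((1 - match_prob) / 3, nrow = 4, ncol = length(cc),
              dimnames = list(bases, NULL))
  m[cbind(match(cc, bases), seq_along(cc))] <- match_prob
  m
}

#' Serialize / read a PWM model as a flat key-value text file
#' @param model A [pwm_model()].
#' @param path File path.
#' @return `read_pwm_model` returns a [pwm_model()].
#' @export
write_pwm_model <- function(model, path) {
  cfg <- list()
  for (box in c("minus35", "minus10"))
    for (b in c("A", "C", "G", "T"))
      cfg[[paste0(box, ".", b)]] <- model[[box]][b, ]
  cfg$spacer_range <- model$spacer_range
  cfg$score_midpoint <- model$score_midpoint
  cfg$score_scale <- model$score_scale
  cfg$background <- model$background
  write_config_file(cfg, path)
}

#' @rdname write_pwm_model
#' @export
read_pwm_model <- function(path) {
  cfg <- read_config_file(path)
  mk <- function(box) {
    m <- rbind(A = cfg[[paste0(box, ".A")]], C = cfg[[paste0(box, ".C")]],
               G = cfg[[paste0(box, ".G")]], T = cfg[[paste0(box, ".T")]])
    sweep(m, 2, colSums(m), "/")
  }
  pwm_model(minus35 = mk("minus35"), minus10 = mk("minus10"),
            spacer_range = cfg$spacer_range,
            score_midpoint = cfg$score_midpoint,
            score_scale = cfg$score_scale,
            background = cfg$background)
}

# per-position summed log-odds of a motif matrix along an encoded sequence;
# positions containing N score -Inf
motif_logodds <- function(enc, lom) {
  w <- ncol(lom)
  n <- length(enc) - w + 1L
  if (n < 1L) return(numeric(0))
  out <- numeric(n)
  for (j in seq_len(w)) {
    v <- lom[enc[j:(j + n - 1L)], j]
    v[is.na(v)] <- -Inf
    out <- out + v
  }
  out
}

scan_one_strand <- function(seqchar, model, threshold = 0) {
  bases <- c("A", "C", "G", "T")
  enc <- match(strsplit(seqchar, "")[[1]], bases)
  lo35m <- log(model$minus35 / model$background)
  lo10m <- log(model$minus10 / model$background)
  w35 <- ncol(lo35m); w10 <- ncol(lo10m)
  lo35 <- motif_logodds(enc, lo35m)
  lo10 <- motif_logodds(enc, lo10m)
  hits <- list()
  for (g in seq(model$spacer_range[1], model$spacer_range[2])) {
    flen <- w35 + g + w10
    n <- nchar(seqchar) - flen + 1L
    if (n < 1L) next
    total <- lo35[seq_len(n)] + lo10[seq_len(n) + w35 + g]
    score01 <- 1 / (1 + exp(-(total - model$score_midpoint) / model$score_scale))
    keep <- which(is.finite(total) & score01 >= threshold)
    if (length(keep))
      hits[[length(hits) + 1L]] <-
        data.frame(start = keep - 1L, flen = flen, score = score01[keep])
  }
  if (!length(hits)) return(NULL)
  do.call(rbind, hits)
}

#' Scan a genome with the built-in sigma70 PWM model
#'
#' Slides paired -35/-10 windows over every allowed spacer length on the
#' forward strand (and, by default, the reverse strand), sums the two boxes'
#' log-odds, maps the sum through the model's logistic calibration to a
#' `[0, 1]` score, and keeps every (position, spacer) hit at or above
#' `threshold`. Deterministic: no randomness is involved. Minus-strand hits
#' are reported in forward-frame coordinates with the motif sequence given
#' on the reading (minus) strand.
#'
#' @param genome An [annotated_genome()].
#' @param model A [pwm_model()].
#' @param threshold Minimum calibrated score kept (default 0.5).
#' @param both_strands Scan the reverse strand too? (default `TRUE`).
#' @return A prediction `data.frame` (`strand`, `start`, `end`, `motif_seq`,
#'   `score`, `source = "builtin_pwm"`), ordered by `start`; empty if the
#'   genome is shorter than the minimal motif + spacer span.
#' @export
scan_builtin_pwm <- function(genome, model = pwm_model(), threshold = 0.5,
                             both_strands = TRUE) {
  stopifnot(inherits(genome, "annotated_genome"), inherits(model, "pwm_model"))
  L <- genome_length(genome)
  res <- list()
  fwd <- scan_one_strand(genome$sequence, model, threshold)
  if (!is.null(fwd)) {
    if (nrow(fwd))
      res$fwd <- data.frame(
        strand = "+", start = fwd$start, end = fwd$start + fwd$flen,
        motif_seq = substring(genome$sequence, fwd$start + 1L,
                              fwd$start + fwd$flen),
        score = fwd$score, source = "builtin_pwm", stringsAsFactors = FALSE)
  }
  if (both_strands) {
    rcseq <- revcomp(genome$sequence)
    rev <- scan_one_strand(rcseq, model, threshold)
    if (!is.null(rev)) {
      if (nrow(rev))
        res$rev <- data.frame(
          strand = "-", start = L - rev$start - rev$flen,
          end = L - rev$start,
          motif_seq = substring(rcseq, rev$start + 1L, rev$start + rev$flen),
          score = rev$score, source = "builtin_pwm", stringsAsFactors = FALSE)
    }
  }
  if (!length(res)) return(empty_predictions())
  preds <- do.call(rbind, res)
  preds <- preds[order(preds$start, preds$end, preds$strand), , drop = FALSE]
  rownames(preds) <- NULL
  preds
}
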