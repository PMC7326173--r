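#' Construct a labelled 2x2 symmetric game
#'
#' @param AA,AB,BA,BB payoff to the row strategy against the column strategy.
#' @param labels character pair of distinct strategy names, row player first.
#' @return A `payoff_matrix`: a 2x2 numeric matrix with strategy dimnames.
#' @examples
#' payoff_matrix(2, 1, 1, 2, labels = c("A", "B"))
#' @export
payoff_matrix <- function(AA, AB, BA, BB, labels = c("A", "B")) {
  entries <- c(AA, AB, BA, BB)
  if (!is.numeric(entries) || length(entries) != 4L || !all(is.finite(entries)))
    stop("payoff entries must be four finite numbers", call. = FALSE)
  if (length(labels) != 2L || !nzchar(labels[1]) || !nzchar(labels[2]) ||
      labels[1] == labels[2])
    stop("strategy labels must be two distinct nonempty strings", call. = FALSE)
  structure(matrix(as.numeric(entries), 2, 2, byrow = TRUE,
                   dimnames = list(labels, labels)),
            class = c("payoff_matrix", "matrix"))
}

#' @export
print.payoff_matrix <- function(x, ...) {
  cat(sprintf("2x2 game: %s vs %s\n", rownames(x)[1], rownames(x)[2]))
  print(unclass(x), ...)
  invisible(x)
}

#' Stage-1 payoff matrix: innovate (V) vs do-not-innovate (D)
#'
#' Cell values follow the model's payoff table. An innovator earns its
#' per-capita discounted market reward over the whole horizon (`b`-share when
#' meeting another innovator, `a`-share against a non-innovator), pays the
#' R&D cost `C`, and collects the expected incentive `P(C) T`. A
#' non-innovator earns 0 against an innovator and bears the per-capita
#' ecological loss `-R_star` against another non-innovator.
#'
#' @param params an [econ_params()] object.
#' @param T_incentive incentive strength; defaults to the value in `params`.
#' @return A [payoff_matrix()] labelled `c("V", "D")`.
#' @export
stage1_payoffs <- function(params, T_incentive = params$T_incentive) {
  stopifnot(inherits(params, "econ_params"))
  if (!is.numeric(T_incentive) || length(T_incentive) != 1L || T_incentive <= 0)
    stop("invalid parameter `T_incentive`: must satisfy T_incentive > 0",
         call. = FALSE)
  tm <- market_share_terms(params)
  inc <- params$P_success * T_incentive
  # the V-vs-D cell uses the a-share over the WHOLE horizon (both reward
  # terms in the table carry the 1 - e^{-r t2} factor)
  k <- params$P_success * (params$C1 - 1) / (params$N * params$r * params$C1)
  a_full <- k * discount_spans(params)$full * params$a * params$R
  pm <- payoff_matrix(
    AA = tm$b_full - params$C + inc,
    AB = a_full - params$C + inc,
    BA = 0,
    BB = -params$R_star,
    labels = c("V", "D")
  )
  attr(pm, "T_incentive") <- T_incentive
  pm
}

#' Stage-2 payoff matrix: leading (L) vs following (F) innovators
#'
#' All participants have adopted the technology; the game is now over who
#' bears the R&D cost of the next advance. A leader facing a leader splits
#' the `b`-share over the whole horizon; a leader facing a follower keeps the
#' monopoly `a`-share during the first period and the `b`-share during the
#' second; a follower facing a leader free-rides on the `b`-share during the
#' second period only and pays no R&D cost; two followers are non-innovators
#' and bear `-R_star`. The incentive is split unevenly: leaders receive
#' `mu * T` and followers `(2 - mu) * T` (mean-preserving at `T`).
#'
#' @param params an [econ_params()] object.
#' @param T_incentive incentive strength; defaults to the value in `params`.
#' @param mu differential coefficient in `[1, 2]`; defaults to `params$mu`.
#' @return A [payoff_matrix()] labelled `c("L", "F")`, with attributes
#'   `T1 = mu * T` and `T2 = (2 - mu) * T`.
#' @export
stage2_payoffs <- function(params, T_incentive = params$T_incentive,
                           mu = params$mu) {
  stopifnot(inherits(params, "econ_params"))
  if (!is.numeric(T_incentive) || length(T_incentive) != 1L || T_incentive <= 0)
    stop("invalid parameter `T_incentive`: must satisfy T_incentive > 0",
         call. = FALSE)
  if (!is.numeric(mu) || length(mu) != 1L || mu < 1 || mu > 2)
    stop("invalid parameter `mu`: must satisfy 1 <= mu <= 2", call. = FALSE)
  tm <- market_share_terms(params)
  P <- params$P_success
  pm <- payoff_matrix(
    AA = tm$b_full - params$C + mu * P * T_incentive,
    AB = tm$a_first + tm$b_second - params$C + mu * P * T_incentive,
    BA = tm$b_second + (2 - mu) * P * T_incentive,
    BB = -params$R_star,
    labels = c("L", "F")
  )
  attr(pm, "T_incentive") <- T_incentive
  attr(pm, "mu") <- mu
  attr(pm, "T1") <- mu * T_incentive
  attr(pm, "T2") <- (2 - mu) * T_incentive
  pm
}

#' Export a payoff matrix to CSV or JSON
#'
#' CSV output is a 2x2 table with strategy labels as header row and column;
#' JSON carries labels, entries and any incentive attributes.
#'
#' @param x a [payoff_matrix()].
#' @param path output file path.
#' @param format `"csv"` or `"json"` (guessed from the extension by default).
#' @return `path`, invisibly.
#' @export
write_payoffs <- function(x, path, format = NULL) {
  stopifnot(inherits(x, "payoff_matrix"))
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  format <- match.arg(format, c("csv", "json"))
  if (format == "csv") {
    df <- data.frame(strategy = rownames(x), unclass(x), check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(labels = rownames(x),
           payoffs = list(AA = x[1, 1], AB = x[1, 2],
                          BA = x[2, 1], BB = x[2, 2]),
           T_incentive = attr(x, "T_incentive"),
           mu = attr(x, "mu")),
      path, auto_unbox = TRUE, digits = I(17))
  }
  invisible(path)
}
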