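#' The sixteen memory-one pure strategies
#'
#' A memory-one pure strategy prescribes cooperate (1) or defect (0) as a
#' function of the previous round's joint state, written
#' `[p_CC, p_CD, p_DC, p_DD]` with the first letter of each state the focal
#' player's own previous move. The index is the big-endian 4-bit encoding
#' `8 p_CC + 4 p_CD + 2 p_DC + 1 p_DD`, so AllD is 0, WSLS (Win-Stay-Lose-Shift)
#' is 9 = `[1,0,0,1]`, Tit-for-Tat is 10 = `[1,0,1,0]` and AllC is 15.
#'
#' @return A tibble with one row per strategy: `index`, `bits` (e.g. `"1001"`),
#'   `name` (canonical alias or `NA`), and the four prescription columns
#'   `p_cc`, `p_cd`, `p_dc`, `p_dd`.
#' @examples
#' strategies()
#' @export
strategies <- function() {
  idx <- 0:15
  digits <- t(vapply(idx, strategy_digits, integer(4)))
  tibble::tibble(
    index = idx,
    bits = apply(digits, 1, paste, collapse = ""),
    name = strategy_name(idx),
    p_cc = digits[, 1], p_cd = digits[, 2], p_dc = digits[, 3], p_dd = digits[, 4]
  )
}

STATES <- c("CC", "CD", "DC", "DD")

.ALIASES <- c(AllD = 0, GT1 = 8, WSLS = 9, TFT = 10, AllC = 15)

#' Canonical strategy names
#' @param index integer vector of strategy indices 0-15.
#' @return Character vector of aliases (`"AllD"`, `"GT1"`, `"WSLS"`, `"TFT"`,
#'   `"AllC"`) or `NA` where no common name exists.
#' @export
strategy_name <- function(index) {
  out <- rep(NA_character_, length(index))
  m <- match(index, .ALIASES)
  out[!is.na(m)] <- names(.ALIASES)[m[!is.na(m)]]
  out
}

#' Decode a strategy index into its four prescriptions
#'
#' @param index integer in 0-15.
#' @return Integer vector `(p_CC, p_CD, p_DC, p_DD)` of 0/1 prescriptions.
#' @examples
#' strategy_digits(9)   # WSLS: 1 0 0 1
#' @export
strategy_digits <- function(index) {
  stopifnot(length(index) == 1L, index == round(index), index >= 0, index <= 15)
  as.integer(c(index %/% 8, index %/% 4, index %/% 2, index) %% 2)
}

#' Encode four prescriptions into a strategy index
#' @param digits integer vector of four 0/1 prescriptions in (CC, CD, DC, DD) order.
#' @return Integer index 0-15; inverse of [strategy_digits()].
#' @export
encode_strategy <- function(digits) {
  stopifnot(length(digits) == 4L, all(digits %in% c(0, 1)))
  as.integer(sum(digits * c(8, 4, 2, 1)))
}

#' Resolve a strategy literal
#'
#' Accepts an index (`9`), a bit-string (`"1001"`), or a canonical alias
#' (`"WSLS"`, case-insensitive) and returns the index.
#'
#' @param x strategy literal.
#' @return Integer index 0-15.
#' @examples
#' as_strategy("WSLS")
#' as_strategy("1001")
#' @export
as_strategy <- function(x) {
  if (is.numeric(x)) {
    stopifnot(length(x) == 1L, x == round(x), x >= 0, x <= 15)
    return(as.integer(x))
  }
  stopifnot(is.character(x), length(x) == 1L)
  al <- .ALIASES[toupper(names(.ALIASES)) == toupper(x)]
  if (length(al) == 1L) return(as.integer(al))
  if (grepl("^[01]{4}$", x)) {
    return(encode_strategy(as.integer(strsplit(x, "")[[1]])))
  }
  if (grepl("^d[0-9]+$", x)) return(as_strategy(as.numeric(sub("^d", "", x))))
  if (grepl("^[0-9]+$", x)) return(as_strategy(as.numeric(x)))
  stop("cannot interpret strategy literal: ", x, call. = FALSE)
}

#' Error-perturbed (effective) strategy
#'
#' With implementation error `epsilon`, an intended move is realised as its
#' opposite with probability `epsilon`, so a pure prescription `d` becomes the
#' cooperation probability `(1 - epsilon) d + epsilon (1 - d)` in every state.
#'
#' @param strategy a strategy literal (index, bit-string or alias).
#' @param epsilon error rate in (0, 1/2]; `epsilon = 0` is allowed here and
#'   returns the pure strategy itself (useful as the error-free limit).
#' @return Named numeric vector of cooperation probabilities over
#'   (CC, CD, DC, DD), each inside `[epsilon, 1 - epsilon]`.
#' @examples
#' perturb_strategy("WSLS", 0.01)
#' @export
perturb_strategy <- function(strategy, epsilon) {
  stopifnot(is.numeric(epsilon), length(epsilon) == 1L, epsilon >= 0, epsilon <= 0.5)
  d <- strategy_digits(as_strategy(strategy))
  stats::setNames((1 - epsilon) * d + epsilon * (1 - d), STATES)
}

#' Swap the two players' perspectives on a joint state
#'
#' `CD` seen by the focal player is `DC` seen by the co-player; `CC` and `DD`
#' are fixed points. The map is an involution.
#'
#' @param state character vector of states among `"CC","CD","DC","DD"`.
#' @return Character vector of swapped states.
#' @export
swap_perspective <- function(state) {
  stopifnot(all(state %in% STATES))
  c(CC = "CC", CD = "DC", DC = "CD", DD = "DD")[state]
}

# state index (1..4) from the co-player's perspective
.SWAP_IDX <- c(1L, 3L, 2L, 4L)

#' Prisoner's Dilemma game parameters
#'
#' The one-shot game is parameterised by the cost of cooperation `c` in (0,1):
#' the focal player's payoff by previous-round state is
#' `P = (1 - c, -c, 1, 0)` over (CC, CD, DC, DD), so cooperation transfers a
#' benefit of 1 at cost `c` and mutual defection pays 0.
#'
#' @param cost cooperation cost, numeric in (0,1) or a `"p/q"` string for exact
#'   work (e.g. `"1/3"`).
#' @return An object of class `ipd_game` with the numeric cost, its exact
#'   rational form, and the payoff vector.
#' @examples
#' game_params(0.2)
#' game_params("16/33")
#' @export
game_params <- function(cost) {
  cr <- as_rational(cost)
  cn <- as.double(cr)
  stopifnot(length(cn) == 1L, cn > 0, cn < 1)
  structure(
    list(cost = cn, cost_rat = cr,
         payoff = stats::setNames(c(1 - cn, -cn, 1, 0), STATES)),
    class = "ipd_game")
}

#' @export
print.ipd_game <- function(x, ...) {
  cat("Iterated PD game: cost c =", format(x$cost_rat),
      "; payoff vector (", paste(signif(x$payoff, 4), collapse = ", "), ")\n")
  invisible(x)
}
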