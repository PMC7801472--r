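# Strategies and the Prisoner's Delight payoff structure.
#
# Internally a strategy is an integer: 0 = "social", 1 = "spiteful".
# The game is normalized so b + c = 1: playing spitefully costs the actor
# c (its payoff drops from 1 to b against a social partner) and removes b
# from the partner (whose payoff drops from 1 to c).

#' Coerce to the internal strategy encoding
#'
#' Strategies are stored as integers: `0` for social, `1` for spiteful.
#' Accepts integers in \{0, 1\}, logicals (`TRUE` = spiteful), or the
#' character labels `"social"` / `"spiteful"` (case-insensitive, partial
#' matching not allowed).
#'
#' @param x vector of strategies in any accepted encoding.
#' @return integer vector of 0s and 1s.
#' @examples
#' as_strategy(c("social", "spiteful"))
#' @export
as_strategy <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (is.character(x)) {
    out <- match(tolower(x), c("social", "spiteful")) - 1L
    if (anyNA(out)) stop("unknown strategy label; use \"social\" or \"spiteful\"")
    return(out)
  }
  if (is.logical(x)) return(as.integer(x))
  if (is.numeric(x)) {
    xi <- as.integer(x)
    if (any(is.na(xi)) || any(xi != x) || any(xi < 0L | xi > 1L))
      stop("numeric strategies must be 0 (social) or 1 (spiteful)")
    return(xi)
  }
  stop("cannot interpret object of class ", class(x)[1L], " as strategies")
}

#' Human-readable strategy labels
#'
#' @param x strategies in any encoding accepted by [as_strategy()].
#' @return character vector of `"social"` / `"spiteful"`.
#' @export
strategy_labels <- function(x) {
  c("social", "spiteful")[as_strategy(x) + 1L]
}

#' Payoff parameters of the Prisoner's Delight
#'
#' Validates the `(b, c)` pair defining the game: `b` is what a spiteful
#' visitor keeps against a social partner (the harm it inflicts removes
#' `b` from the partner), `c` is what a social agent keeps when paired with
#' a spiteful one (the cost of spite to its actor). The game is normalized
#' by `b + c = 1`, so the four payoffs are fully determined:
#' social-social = 1, social-vs-spiteful = c, spiteful-vs-social = b,
#' spiteful-spiteful = 0.
#'
#' Spite can only pay its way when the harm exceeds the cost (`b > c`);
#' `b <= c` is permitted for boundary exploration but triggers a warning.
#'
#' @param b spiteful-vs-social payoff, in (0, 1).
#' @param c social-vs-spiteful payoff, in (0, 1).
#' @param normalize if `TRUE`, rescale `(b, c)` by `1/(b + c)` before
#'   validation instead of requiring `b + c = 1` on input.
#' @return an object of class `"payoff_params"`: a list with elements `b`
#'   and `c`.
#' @examples
#' payoff_params(10 / 11, 1 / 11)
#' payoff_params(10, 1, normalize = TRUE)
#' @export
payoff_params <- function(b, c, normalize = FALSE) {
  stopifnot(is.numeric(b), length(b) == 1L, is.finite(b),
            is.numeric(c), length(c) == 1L, is.finite(c))
  if (normalize) {
    s <- b + c
    if (s <= 0) stop("cannot normalize: b + c must be positive")
    b <- b / s
    c <- c / s
  }
  if (b <= 0 || c <= 0) stop("b and c must be strictly positive")
  if (abs(b + c - 1) > 1e-12)
    stop("b + c must equal 1 (got ", format(b + c, digits = 15),
         "); use normalize = TRUE to rescale")
  if (b <= c)
    warning("b <= c: spiteful harm does not exceed its cost; ",
            "spite cannot gain a relative advantage in this regime")
  structure(list(b = b, c = c), class = "payoff_params")
}

#' @export
print.payoff_params <- function(x, ...) {
  cat(sprintf("Prisoner's Delight payoffs: b = %.6g, c = %.6g (b/c = %.4g)\n",
              x$b, x$c, x$b / x$c))
  invisible(x)
}

#' Prisoner's Delight payoff
#'
#' Payoff received by an agent playing `own` against a partner playing
#' `other`. Vectorized over both arguments. The game is symmetric in roles:
#' both participants of an interaction are evaluated with this same
#' function (visitor and host roles matter for learning, not for payoffs).
#'
#' @param own,other strategies in any encoding accepted by [as_strategy()].
#' @param params a [payoff_params()] object.
#' @return numeric payoff(s) in `[0, 1]`.
#' @examples
#' p <- payoff_params(10 / 11, 1 / 11)
#' payoff("social", "social", p)    # 1
#' payoff("spiteful", "social", p)  # b
#' payoff("social", "spiteful", p)  # c
#' @export
payoff <- function(own, other, params) {
  stopifnot(inherits(params, "payoff_params"))
  own <- as_strategy(own)
  other <- as_strategy(other)
  1 - params$c * own - params$b * other
}

#' Full payoff matrix of the game
#'
#' @param params a [payoff_params()] object.
#' @return 2x2 numeric matrix, rows = own strategy, columns = partner
#'   strategy, dimnames `social`/`spiteful`.
#' @export
payoff_matrix <- function(params) {
  m <- outer(0:1, 0:1, function(i, j) 1 - params$c * i - params$b * j)
  dimnames(m) <- list(own = c("social", "spiteful"),
                      other = c("social", "spiteful"))
  m
}
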