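# Built-in benchmark systems, each shipped with its standard initial state,
# simulation horizon and canonical histogram bin widths.

#' Built-in benchmark reaction systems
#'
#' Returns one of the bundled test systems together with its standard
#' initial state, horizon and histogram bin widths:
#' \describe{
#'   \item{chain_decay}{X1 -> X2 -> X3, c = 1, 1; X(0) = (10000, 1, 0),
#'     T = 5; bins 2, 5, 5.}
#'   \item{michaelis_menten}{enzyme kinetics, c = 1e-4, 0.5, 0.5;
#'     X(0) = (1000, 200, 2000, 0), T = 10; bins 5, 5, 5, 5.}
#'   \item{schlogl}{the bimodal Schlogl system, c = 3e-7, 1e-4, 1e-3, 3.5
#'     with A = 1e5 and B = 2e5 buffered; X(0) = 250, T = 10; bin 10.}
#'   \item{enzymes}{mutually inhibiting enzymes, 8 species / 12 reactions;
#'     X(0) = (20000, 15000, 9500, 9500, 2000, 500, 2000, 500), T = 2;
#'     bins 100, 100, 50, 50, 50, 50, 50, 50.}
#'   \item{yule}{the linear pure-birth system X -> 2X, c = 0.2,
#'     X(0) = 1000, T = 12 (order studies).}
#'   \item{annihilation}{the non-linear system X + Y -> 0, c = 1e-5,
#'     X(0) = Y(0) = 10000, T = 12 (order studies).}
#'   \item{birth_death}{0 -> X (c = 5), X -> 0 (c = 1): Poisson(5)
#'     stationary law, used as an exactness toy.}
#' }
#'
#' @param name fixture name (see Details).
#' @return list with components \code{sys} (\linkS4class{ReactionSystem}),
#'   \code{x0} (initial counts), \code{T} (horizon) and \code{bins}
#'   (histogram bin width per species).
#' @examples
#' fx <- builtinFixture("chain_decay")
#' fx$sys
#' @export
builtinFixture <- function(name = c("chain_decay", "michaelis_menten",
                                    "schlogl", "enzymes", "yule",
                                    "annihilation", "birth_death")) {
  name <- match.arg(name)
  switch(name,
    chain_decay = list(
      sys = reactionSystem(
        species = c("X1", "X2", "X3"),
        reactions = list(
          list(name = "r1", reactants = c(X1 = 1), products = c(X2 = 1), c = 1),
          list(name = "r2", reactants = c(X2 = 1), products = c(X3 = 1), c = 1))),
      x0 = c(10000, 1, 0), T = 5, bins = c(2, 5, 5)),
    michaelis_menten = list(
      sys = reactionSystem(
        species = c("X1", "X2", "X3", "X4"),
        reactions = list(
          list(name = "bind",  reactants = c(X1 = 1, X2 = 1),
               products = c(X3 = 1), c = 1e-4),
          list(name = "unbind", reactants = c(X3 = 1),
               products = c(X1 = 1, X2 = 1), c = 0.5),
          list(name = "cat",   reactants = c(X3 = 1),
               products = c(X2 = 1, X4 = 1), c = 0.5))),
      x0 = c(1000, 200, 2000, 0), T = 10, bins = c(5, 5, 5, 5)),
    schlogl = list(
      sys = reactionSystem(
        species = c("X", "A", "B"),
        fixed = c("A", "B"),
        reactions = list(
          list(name = "r1", reactants = c(A = 1, X = 2), products = c(X = 3),
               c = 3e-7),
          list(name = "r2", reactants = c(X = 3), products = c(A = 1, X = 2),
               c = 1e-4),
          list(name = "r3", reactants = c(B = 1), products = c(X = 1),
               c = 1e-3),
          list(name = "r4", reactants = c(X = 1), products = c(B = 1),
               c = 3.5))),
      x0 = c(250, 1e5, 2e5), T = 10, bins = c(10, NA, NA)),
    enzymes = list(
      sys = reactionSystem(
        species = c("A", "B", "EA", "EB", "EAB", "EAB2", "EBA", "EBA2"),
        reactions = list(
          list(name = "prodA",  reactants = c(EA = 1),
               products = c(EA = 1, A = 1), c = 15),
          list(name = "prodB",  reactants = c(EB = 1),
               products = c(EB = 1, B = 1), c = 15),
          list(name = "inhA1",  reactants = c(EA = 1, B = 1),
               products = c(EAB = 1), c = 5e-4, cRev = 2),
          list(name = "inhA2",  reactants = c(EAB = 1, B = 1),
               products = c(EAB2 = 1), c = 1e-3, cRev = 6),
          list(name = "degA",   reactants = c(A = 1), products = NULL, c = 5),
          list(name = "inhB1",  reactants = c(EB = 1, A = 1),
               products = c(EBA = 1), c = 5e-4, cRev = 2),
          list(name = "inhB2",  reactants = c(EBA = 1, A = 1),
               products = c(EBA2 = 1), c = 1e-3, cRev = 6),
          list(name = "degB",   reactants = c(B = 1), products = NULL, c = 5))),
      x0 = c(20000, 15000, 9500, 9500, 2000, 500, 2000, 500), T = 2,
      bins = c(100, 100, 50, 50, 50, 50, 50, 50)),
    yule = list(
      sys = reactionSystem(
        species = "X",
        reactions = list(
          list(name = "birth", reactants = c(X = 1), products = c(X = 2),
               c = 0.2))),
      x0 = 1000, T = 12, bins = 50),
    annihilation = list(
      sys = reactionSystem(
        species = c("X", "Y"),
        reactions = list(
          list(name = "annihilate", reactants = c(X = 1, Y = 1),
               products = NULL, c = 1e-5))),
      x0 = c(10000, 10000), T = 12, bins = c(50, 50)),
    birth_death = list(
      sys = reactionSystem(
        species = "X",
        reactions = list(
          list(name = "in",  reactants = NULL, products = c(X = 1), c = 5),
          list(name = "out", reactants = c(X = 1), products = NULL, c = 1))),
      x0 = 0, T = 10, bins = 1)
  )
}

#' @rdname builtinFixture
#' @return \code{builtinFixtureNames}: character vector of fixture names.
#' @export
builtinFixtureNames <- function() {
  c("chain_decay", "michaelis_menten", "schlogl", "enzymes", "yule",
    "annihilation", "birth_death")
}
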