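# Plain-text model format, trajectory/ensemble export and the command-line
# entry point.
#
# Model grammar (one statement per line, '#' starts a comment):
#   species <name> <name> ...
#   init    <count> <count> ...        (same order as species)
#   fixed   <name> ...                 (optional)
#   T       <horizon>
#   k <name> : <m> A + <n> B -> <p> C ; c=<value>
#   k <name> : A + B <-> C ; c=<forward>, <reverse>
# An empty side is written '0'.  Reversible reactions expand into two
# irreversible ones, forward constant first.

.parseSide <- function(txt, line) {
  txt <- trimws(txt)
  if (txt == "0" || txt == "") return(NULL)
  terms <- strsplit(txt, "\\+")[[1]]
  out <- integer(0)
  for (tm in terms) {
    tm <- trimws(tm)
    mm <- regmatches(tm, regexec("^([0-9]+)?\\s*([A-Za-z_][A-Za-z0-9_]*)$",
                                 tm))[[1]]
    if (length(mm) == 0L)
      stop("line ", line, ": cannot parse species term '", tm, "'")
    mult <- if (nzchar(mm[2])) as.integer(mm[2]) else 1L
    sp <- mm[3]
    out[sp] <- (if (sp %in% names(out)) out[[sp]] else 0L) + mult
  }
  out
}

#' Read a reaction-network model file
#'
#' Parses the plain-text model grammar (see the package source header of
#' \code{io.R} or any bundled model under
#' \code{system.file("extdata/models", package = "StochBS")}) into a
#' \linkS4class{ReactionSystem} with its initial state and horizon.
#'
#' @param path file path.
#' @return list with \code{sys}, \code{x0}, \code{T}.
#' @export
parseModelFile <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path)
  lines <- readLines(path)
  species <- character(0); init <- numeric(0); fixed <- character(0)
  horizon <- NA_real_
  reactions <- list()
  for (ln in seq_along(lines)) {
    raw <- sub("#.*$", "", lines[ln])
    txt <- trimws(raw)
    if (!nzchar(txt)) next
    if (grepl("^species\\s", txt)) {
      species <- strsplit(trimws(sub("^species", "", txt)), "\\s+")[[1]]
    } else if (grepl("^init\\s", txt)) {
      init <- as.numeric(strsplit(trimws(sub("^init", "", txt)), "\\s+")[[1]])
    } else if (grepl("^fixed\\s", txt)) {
      fixed <- strsplit(trimws(sub("^fixed", "", txt)), "\\s+")[[1]]
    } else if (grepl("^T\\s", txt)) {
      horizon <- as.numeric(trimws(sub("^T", "", txt)))
    } else if (grepl("^k\\s", txt)) {
      body <- trimws(sub("^k", "", txt))
      halves <- strsplit(body, ";")[[1]]
      if (length(halves) != 2L)
        stop("line ", ln, ": expected '; c=...' clause")
      cTxt <- trimws(halves[2])
      if (!grepl("^c\\s*=", cTxt))
        stop("line ", ln, ": expected 'c=' in rate clause")
      cVals <- as.numeric(strsplit(sub("^c\\s*=", "", cTxt), ",")[[1]])
      head <- strsplit(halves[1], ":")[[1]]
      if (length(head) != 2L)
        stop("line ", ln, ": expected '<name> : <reaction>'")
      name <- trimws(head[1])
      rev <- grepl("<->", head[2], fixed = TRUE)
      sides <- strsplit(head[2], if (rev) "<->" else "->", fixed = TRUE)[[1]]
      if (length(sides) != 2L)
        stop("line ", ln, ": expected exactly one arrow")
      if (rev && length(cVals) != 2L)
        stop("line ", ln, ": reversible reaction needs c=<fwd>, <rev>")
      if (!rev && length(cVals) != 1L)
        stop("line ", ln, ": irreversible reaction takes a single c")
      reactions[[length(reactions) + 1L]] <- list(
        name = name,
        reactants = .parseSide(sides[1], ln),
        products = .parseSide(sides[2], ln),
        c = cVals[1],
        cRev = if (rev) cVals[2] else NULL)
    } else stop("line ", ln, ": unrecognised statement '", txt, "'")
  }
  if (length(species) == 0L) stop("model file declares no species")
  if (length(init) != length(species))
    stop("init stanza length does not match species")
  if (is.na(horizon)) stop("model file declares no horizon T")
  sys <- reactionSystem(species, reactions, fixed)
  list(sys = sys, x0 = init, T = horizon)
}

#' Write a reaction-network model file
#'
#' Emits the canonical plain-text form; \code{parseModelFile} of the
#' result reproduces the system exactly (reversible reactions are written
#' in their expanded irreversible form).
#'
#' @param sys a \linkS4class{ReactionSystem}.
#' @param x0 initial counts.
#' @param T horizon.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeModelFile <- function(sys, x0, T, path) {
  side <- function(v) {
    idx <- which(v > 0L)
    if (!length(idx)) return("0")
    paste(sprintf("%d %s", v[idx], sys@speciesNames[idx]), collapse = " + ")
  }
  lines <- c(
    paste("species", paste(sys@speciesNames, collapse = " ")),
    paste("init", paste(format(x0, scientific = FALSE, trim = TRUE),
                        collapse = " ")),
    if (any(sys@fixedSpecies))
      paste("fixed", paste(sys@speciesNames[sys@fixedSpecies],
                           collapse = " ")),
    paste("T", format(T, trim = TRUE)),
    vapply(seq_len(nReactions(sys)), function(j) {
      lhs <- sys@reactantOrders[, j]
      rhs <- sys@reactantOrders[, j] + sys@netChange[, j]
      sprintf("k %s : %s -> %s ; c=%.17g", sys@reactionNames[j],
              side(lhs), side(rhs), sys@rateConstants[j])
    }, character(1)))
  writeLines(lines, path)
  invisible(path)
}

# FNV-1a hash of a character vector, for run-manifest fingerprints.
# Kept in unsigned 32-bit arithmetic; bitwXor needs the signed view.
.manifestHash <- function(lines) {
  h <- 2166136261
  p <- 16777619
  for (b in utf8ToInt(paste(lines, collapse = "\n"))) {
    hs <- bitwXor(as.integer(h - if (h >= 2^31) 2^32 else 0), b)
    h <- if (hs < 0) hs + 2^32 else hs
    # multiply mod 2^32 in 16-bit halves to stay exact in doubles
    lo <- h %% 65536
    hi <- (h - lo) / 65536
    h <- (lo * p + ((hi * p) %% 65536) * 65536) %% 4294967296
  }
  lo <- h %% 65536
  sprintf("%04x%04x", as.integer((h - lo) / 65536), as.integer(lo))
}

# delimited table with a '# key: value' manifest header
.writeManifestTable <- function(df, path, manifest) {
  lines <- sprintf("# %s: %s", names(manifest), unlist(manifest))
  lines <- c(lines, sprintf("# manifest_hash: %s", .manifestHash(lines)))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(lines, con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.readManifestTable <- function(path) {
  lines <- readLines(path)
  hdr <- grepl("^#", lines)
  read.table(text = lines[!hdr], header = TRUE, sep = "\t")
}

#' Command-line interface
#'
#' Thin shell over the package functions, invoked by the bundled
#' \code{inst/scripts/stochbs} Rscript.  Subcommands:
#' \describe{
#'   \item{simulate}{\code{--fixture <name>} or \code{--model <file>},
#'     \code{--method ssa|tl|sbs|sbsda|ubtl}, \code{--n}, \code{--seed},
#'     \code{--t-end}, \code{--out}, plus solver flags (\code{--s1},
#'     \code{--s2}, \code{--atol}, \code{--rtol}, \code{--kmax},
#'     \code{--tau0}, \code{--eps}).  Writes a final-state ensemble table
#'     with a run manifest.}
#'   \item{analyze}{\code{--ens <file> --ref <file> --bins w1,w2,...
#'     --out <file>}: per-species histogram L1 errors on identical bins.}
#'   \item{order-study}{\code{--system yule|annihilation --method
#'     sbs|sbsda|tl --k <col> --taus t1,t2,... --out <file>}: fixed-step
#'     weak-order slopes.}
#'   \item{fixtures}{lists the bundled systems; \code{--export <dir>}
#'     writes their model files.}
#' }
#'
#' @param argv character vector of arguments (as from
#'   \code{commandArgs(trailingOnly = TRUE)}).
#' @return integer exit status (0 on success), invisibly.
#' @export
runCli <- function(argv) {
  fail <- function(...) { message(...); invisible(1L) }
  if (length(argv) == 0L)
    return(fail("usage: stochbs <simulate|analyze|order-study|fixtures> ..."))
  cmd <- argv[1]
  opts <- .parseFlags(argv[-1])
  getOpt <- function(name, default = NULL) {
    if (name %in% names(opts)) opts[[name]] else default
  }

  if (cmd == "simulate") {
    method <- getOpt("method")
    if (is.null(method) ||
        !method %in% c("ssa", "tl", "sbs", "sbsda", "ubtl"))
      return(fail("simulate: --method must be ssa|tl|sbs|sbsda|ubtl"))
    model <- if (!is.null(getOpt("fixture"))) {
      if (!getOpt("fixture") %in% builtinFixtureNames())
        return(fail("unknown fixture '", getOpt("fixture"), "'"))
      builtinFixture(getOpt("fixture"))
    } else if (!is.null(getOpt("model"))) {
      parseModelFile(getOpt("model"))
    } else return(fail("simulate: need --fixture or --model"))
    n <- as.integer(getOpt("n", 100))
    seed <- as.integer(getOpt("seed", 1))
    T <- as.numeric(getOpt("t-end", model$T))
    settings <- solverSettings(
      s1 = as.numeric(getOpt("s1", 0.25)),
      s2 = as.numeric(getOpt("s2", 0.25)),
      atol = as.numeric(getOpt("atol", 1e-6)),
      rtol = as.numeric(getOpt("rtol", 1e-6)),
      kMax = as.integer(getOpt("kmax", 8)),
      tau0 = as.numeric(getOpt("tau0", NA)),
      epsilon = as.numeric(getOpt("eps", 0.05)))
    ens <- simulateEnsemble(model$sys, model$x0, T, method, n, settings,
                            seed)
    out <- getOpt("out", "ensemble.tsv")
    manifest <- list(kind = "final-state-ensemble", method = method,
                     n = n, seed = seed, T = T,
                     species = paste(speciesNames(model$sys),
                                     collapse = ","),
                     s1 = settings@s1, s2 = settings@s2,
                     atol = settings@atol, rtol = settings@rtol,
                     kMax = settings@kMax, epsilon = settings@epsilon,
                     package = as.character(
                       utils::packageVersion("StochBS")))
    .writeManifestTable(as.data.frame(ens), out, manifest)
    message("wrote ", out)
    return(invisible(0L))
  }

  if (cmd == "analyze") {
    ensPath <- getOpt("ens"); refPath <- getOpt("ref")
    if (is.null(ensPath) || is.null(refPath))
      return(fail("analyze: need --ens and --ref"))
    if (!file.exists(refPath)) return(fail("missing reference ", refPath))
    ens <- as.matrix(.readManifestTable(ensPath))
    ref <- as.matrix(.readManifestTable(refPath))
    bins <- as.numeric(strsplit(getOpt("bins", "1"), ",")[[1]])
    if (length(bins) == 1L) bins <- rep(bins, ncol(ens))
    errs <- ensembleL1Errors(ens, ref, bins)
    df <- data.frame(species = colnames(ens), binWidth = bins[seq_len(ncol(ens))],
                     l1 = errs)
    out <- getOpt("out", "")
    if (nzchar(out))
      .writeManifestTable(df, out, list(kind = "histogram-errors",
                                        ens = ensPath, ref = refPath))
    else print(df)
    return(invisible(0L))
  }

  if (cmd == "order-study") {
    system <- getOpt("system", "yule")
    method <- getOpt("method", "sbs")
    k <- as.integer(getOpt("k", 1))
    if (!system %in% c("yule", "annihilation"))
      return(fail("order-study: --system must be yule|annihilation"))
    if (!method %in% c("sbs", "sbsda", "tl"))
      return(fail("order-study: --method must be sbs|sbsda|tl"))
    if (system == "yule") {
      fx <- builtinFixture("yule")
      taus <- as.numeric(strsplit(
        getOpt("taus", "1.5,1,0.75,0.5,0.375,0.25"), ",")[[1]])
      st <- linearOrderStudy(fx$sys, fx$x0, fx$T, taus, method, k)
    } else {
      sys <- reactionSystem(c("X", "Y"),
        list(list(name = "annihilate", reactants = c(X = 1, Y = 1),
                  products = NULL, c = 5e-4)))
      taus <- as.numeric(strsplit(getOpt("taus", "1.5,0.75,0.375,0.1875"),
                                  ",")[[1]])
      st <- chainOrderStudy(sys, c(200, 200), 12, taus, method, k)
    }
    df <- data.frame(tau = st$taus, error = st$errors)
    message(sprintf("weak-order slope (%s, %s, k=%d): %.4f",
                    system, method, k, st$slope))
    out <- getOpt("out", "")
    if (nzchar(out))
      .writeManifestTable(df, out,
                          list(kind = "order-study", system = system,
                               method = method, k = k,
                               slope = sprintf("%.6f", st$slope)))
    return(invisible(0L))
  }

  if (cmd == "fixtures") {
    dir <- getOpt("export")
    for (nm in builtinFixtureNames()) {
      fx <- builtinFixture(nm)
      message(sprintf("%-18s %d species, %d reactions, T=%g", nm,
                      nSpecies(fx$sys), nReactions(fx$sys), fx$T))
      if (!is.null(dir)) {
        dir.create(dir, showWarnings = FALSE, recursive = TRUE)
        writeModelFile(fx$sys, fx$x0, fx$T, file.path(dir,
                                                      paste0(nm, ".txt")))
      }
    }
    return(invisible(0L))
  }

  fail("unknown subcommand '", cmd, "'")
}

.parseFlags <- function(args) {
  out <- list()
  i <- 1L
  while (i <= length(args)) {
    a <- args[i]
    if (!grepl("^--", a)) stop("unexpected argument '", a, "'")
    key <- sub("^--", "", a)
    if (i == length(args) || grepl("^--", args[i + 1L])) {
      out[[key]] <- TRUE; i <- i + 1L
    } else {
      out[[key]] <- args[i + 1L]; i <- i + 2L
    }
  }
  out
}
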