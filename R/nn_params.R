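#' Nearest-neighbor thermodynamic parameter set
#'
#' Loads the published nearest-neighbor enthalpy/entropy tables used by the
#' duplex model:
#'
#' * Watson-Crick stacks: the unified oligonucleotide parameters of
#'   SantaLucia (1998) / Allawi & SantaLucia (1997) -- ten doublet stacks
#'   plus terminal A/T and G/C duplex-initiation terms, at the 1 M NaCl
#'   reference condition.
#' * Single internal mismatches: Allawi & SantaLucia (1997, 1998) and
#'   Peyret et al. (1999) trimer-context doublets, one mismatched pair per
#'   doublet.
#' * Terminal mismatches: the DNA terminal-mismatch doublets of
#'   SantaLucia & Peyret (2001).
#'
#' Doublet keys follow the conventional `"XY/WZ"` notation: the top strand
#' `XY` is written 5'->3', the bottom strand `WZ` 3'->5', so `X` pairs (or
#' mispairs) with `W`. A duplex doublet and its rotated equivalent
#' (`"ZW/YX"`) denote the same physical stack; lookups resolve either form.
#'
#' @param wc,internal_mm,terminal_mm optional paths to replacement parameter
#'   files (CSV with columns `stack`, `dh_kcal`, `ds_cal`), allowing
#'   alternative published tables to be swapped in.
#' @param source_label free-text provenance string stored with the set.
#' @return an object of class `nn_parameter_set` with components
#'   `wc`, `internal_mm`, `terminal_mm` (named lookup environments of
#'   `c(dh, ds)` vectors), `init_at`, `init_gc`, and `source_label`.
#'   Enthalpies are kcal/mol, entropies cal/(mol K).
#' @examples
#' p <- nn_params()
#' p$init_at
#' @export
nn_params <- function(wc = NULL, internal_mm = NULL, terminal_mm = NULL,
                      source_label = paste(
                        "Watson-Crick: unified NN parameters, SantaLucia (1998);",
                        "internal mismatches: Allawi & SantaLucia (1997-1998),",
                        "Peyret et al. (1999);",
                        "terminal mismatches: SantaLucia & Peyret (2001)")) {
  path <- function(p, default) {
    if (!is.null(p)) p else system.file("extdata", "nn", default,
                                        package = "hseprobe", mustWork = TRUE)
  }
  read_tab <- function(f) {
    d <- utils::read.csv(f, stringsAsFactors = FALSE)
    stopifnot(all(c("stack", "dh_kcal", "ds_cal") %in% names(d)))
    e <- new.env(parent = emptyenv())
    for (i in seq_len(nrow(d))) {
      assign(d$stack[i], c(dh = d$dh_kcal[i], ds = d$ds_cal[i]), envir = e)
    }
    e
  }
  wc_env <- read_tab(path(wc, "watson_crick.csv"))
  init_at <- get("init_A/T", envir = wc_env)
  init_gc <- get("init_G/C", envir = wc_env)
  rm(list = c("init_A/T", "init_G/C"), envir = wc_env)
  obj <- structure(
    list(
      wc = wc_env,
      internal_mm = read_tab(path(internal_mm, "internal_mismatch.csv")),
      terminal_mm = read_tab(path(terminal_mm, "terminal_mismatch.csv")),
      init_at = init_at,
      init_gc = init_gc,
      source_label = source_label
    ),
    class = "nn_parameter_set"
  )
  validate_nn_params(obj)
  obj
}

# A rotated doublet key: 5'XY3'/3'WZ5' read from the other strand is
# 5'ZW3'/3'YX5'; as a string that is the full reversal of "XY/WZ".
rotate_key <- function(key) str_rev(key)

validate_nn_params <- function(p) {
  for (key in ls(p$wc)) {
    v <- get(key, envir = p$wc)
    if (v[["dh"]] >= 0) {
      stop("Watson-Crick stack ", key, " has non-negative enthalpy (",
           v[["dh"]], " kcal/mol); duplex formation must be exothermic",
           call. = FALSE)
    }
    alt <- rotate_key(key)
    if (alt != key && exists(alt, envir = p$wc)) {
      w <- get(alt, envir = p$wc)
      if (!isTRUE(all.equal(v, w))) {
        stop("Watson-Crick table not closed under strand rotation: ",
             key, " vs ", alt, call. = FALSE)
      }
    }
  }
  invisible(p)
}

# Look up a doublet in one table environment, trying the rotated key too.
# Returns c(dh, ds) or NULL.
lookup_doublet <- function(env, key) {
  if (exists(key, envir = env)) return(get(key, envir = env))
  alt <- rotate_key(key)
  if (exists(alt, envir = env)) return(get(alt, envir = env))
  NULL
}

#' @export
print.nn_parameter_set <- function(x, ...) {
  cat("Nearest-neighbor parameter set\n")
  cat("  Watson-Crick stacks:  ", length(ls(x$wc)), "\n")
  cat("  internal mismatches:  ", length(ls(x$internal_mm)), "\n")
  cat("  terminal mismatches:  ", length(ls(x$terminal_mm)), "\n")
  cat("  source:", x$source_label, "\n")
  invisible(x)
}

#' Stack lookup for a probe/target doublet
#'
#' Resolves the enthalpy/entropy contribution of one adjacent base-pair
#' doublet. `kind` selects the table: fully matched doublets use the
#' Watson-Crick table, doublets containing the single mismatch use the
#' internal- or terminal-mismatch table. A missing entry is a hard error --
#' the engine never silently substitutes zero.
#'
#' @param params an [nn_params()] object.
#' @param probe_doublet two probe bases, 5'->3'.
#' @param target_doublet the two opposing target bases, 3'->5'.
#' @param kind `"wc"`, `"internal_mm"` or `"terminal_mm"`.
#' @return numeric `c(dh, ds)`.
#' @export
stack_params <- function(params, probe_doublet, target_doublet,
                         kind = c("wc", "internal_mm", "terminal_mm")) {
  kind <- match.arg(kind)
  key <- paste0(probe_doublet, "/", target_doublet)
  v <- lookup_doublet(params[[kind]], key)
  if (is.null(v)) {
    stop("no ", gsub("_", " ", kind), " parameters for doublet ", key,
         " (or its rotation ", rotate_key(key), ")", call. = FALSE)
  }
  v
}
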