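# Model parameters: canonical keys, display names, defaults, validation.

# One row per model constant. `display` is the conventional published name
# (capitalisation kept as printed, including the Thx/THx inconsistency);
# `key` is the canonical snake_case identifier used throughout the package;
# `nonneg` marks quantities that must not be negative (pulse intensities may
# be negative: a negative therapy intensity models an *influx* of cells).
.param_def <- function() {
  L <- list(
    # key                      display                          default  nonneg
    c("csc_cap",               "CSC cap",                       1e-9,    TRUE),
    c("csc_death",             "CSC death",                     0.01,    TRUE),
    c("csc_diff",              "CSC diff",                      0.002,   TRUE),
    c("csc_growth",            "CSC growth",                    0.01,    TRUE),
    c("csc_thx_dur",           "CSC Thx dur",                   100,     TRUE),
    c("csc_thx_intens",        "CSC THx intens",                0,       FALSE),
    c("csc_thx_time",          "CSC THx time",                  400,     TRUE),
    c("ctac_cap",              "CTAC cap",                      1e-9,    TRUE),
    c("ctac_death",            "CTAC death",                    0.03,    TRUE),
    c("ctac_diff",             "CTAC diff",                     0.91,    TRUE),
    c("ctac_growth",           "CTAC growth",                   0.9,     TRUE),
    c("ctac_thx_dur",          "CTAC Thx dur",                  100,     TRUE),
    c("ctac_thx_intens",       "CTAC THx intens",               0,       FALSE),
    c("ctac_thx_time",         "CTAC THx time",                 400,     TRUE),
    c("help_for_csc",          "Help for CSC",                  0.001,   TRUE),
    c("help_for_ctac",         "Help for CTAC",                 0.001,   TRUE),
    c("help_for_killer",       "Help for Killer Cells",         1e-5,    TRUE),
    c("help_for_mtc",          "Help for MTC",                  0.001,   TRUE),
    c("helper_cap",            "Helper cap",                    1e-9,    TRUE),
    c("helper_death",          "Helper death",                  1e-5,    TRUE),
    c("helper_stim_by_csc",    "Helper stim by CSC",            0.001,   TRUE),
    c("helper_stim_by_ctac",   "Helper stim by CTAC",           0.001,   TRUE),
    c("helper_stim_by_mtc",    "Helper stim by MTC",            0.001,   TRUE),
    c("helper_thx_dur",        "Helper Thx dur",                100,     TRUE),
    c("helper_thx_intens",     "Helper THx intens",             0,       FALSE),
    c("helper_thx_time",       "Helper THx time",               400,     TRUE),
    c("immuno1_dur",           "ImmunoTHx1 dur",                1,       TRUE),
    c("immuno1_intens",        "ImmunoTHx1 intens",             0,       FALSE),
    c("immuno1_time",          "ImmunoTHx1 time",               300,     TRUE),
    c("immuno2_csc_dur",       "ImmunoTHx2CSC dur",             3000,    TRUE),
    c("immuno2_csc_intens",    "ImmunoTHx2CSC intens",          0,       FALSE),
    c("immuno2_csc_time",      "ImmunoTHx2CSC time",            1000,    TRUE),
    c("immuno2_ctac_dur",      "ImmunoTHx2CTAC dur",            3000,    TRUE),
    c("immuno2_ctac_intens",   "ImmunoTHx2CTAC intens",         0,       FALSE),
    c("immuno2_ctac_time",     "ImmunoTHx2CTAC time",           1000,    TRUE),
    c("immuno2_mtc_dur",       "ImmunoTHx2MTC dur",             3000,    TRUE),
    c("immuno2_mtc_intens",    "ImmunoTHx2MTC intens",          0,       FALSE),
    c("immuno2_mtc_time",      "ImmunoTHx2MTC time",            1000,    TRUE),
    c("initial_csc",           "Initial CSC",                   10,      TRUE),
    c("initial_ctac",          "Initial CTAC",                  10,      TRUE),
    c("initial_helper",        "Initial Helper Cells",          10,      TRUE),
    c("initial_killer",        "Initial Killer Cells",          10,      TRUE),
    c("initial_mtc",           "Initial MTC",                   10,      TRUE),
    c("initial_regulator",     "Initial Regulatory Cells",      10,      TRUE),
    c("killer_cap",            "Killer cap",                    1e-9,    TRUE),
    c("killer_death",          "Killer death",                  1e-5,    TRUE),
    c("killer_stim_by_csc",    "Killer stim by CSC",            1e-4,    TRUE),
    c("killer_stim_by_ctac",   "Killer stim by CTAC",           1e-4,    TRUE),
    c("killer_stim_by_mtc",    "Killer stim by MTC",            0.02,    TRUE),
    c("killer_thx_dur",        "Killer THx dur",                100,     TRUE),
    c("killer_thx_intens",     "Killer THx intens",             0,       FALSE),
    c("killer_thx_time",       "Killer THx time",               400,     TRUE),
    c("kill_of_csc",           "Kill of CSC",                   1e-6,    TRUE),
    c("kill_of_ctac",          "Kill of CTAC",                  1e-6,    TRUE),
    c("kill_of_mtc",           "Kill of MTC",                   1e-6,    TRUE),
    c("mtc_cap",               "MTC cap",                       1e-9,    TRUE),
    c("mtc_death",             "MTC death",                     0.5,     TRUE),
    c("mtc_growth",            "MTC growth",                    0,       TRUE),
    c("mtc_thx_dur",           "MTC Thx dur",                   100,     TRUE),
    c("mtc_thx_intens",        "MTC THx intens",                0,       FALSE),
    c("mtc_thx_time",          "MTC THx time",                  400,     TRUE),
    c("regulation_of_helper",  "Regulation of Helper Cells",    1e-4,    TRUE),
    c("regulation_of_killer",  "Regulation of Killer Cells",    0.5,     TRUE),
    c("regulator_cap",         "Regulator cap",                 1e-4,    TRUE),
    c("regulator_death",       "Regulator death",               1e-5,    TRUE),
    c("regulator_stim_by_csc", "Regulator stim by CSC",         0.001,   TRUE),
    c("regulator_stim_by_ctac","Regulator stim by CTAC",        0.001,   TRUE),
    c("regulator_stim_by_mtc", "Regulator stim by MTC",         1e-4,    TRUE),
    c("regulator_thx_dur",     "Regulator Thx dur",             100,     TRUE),
    c("regulator_thx_intens",  "Regulator THx intens",          0,       FALSE),
    c("regulator_thx_time",    "Regulator THx time",            400,     TRUE)
  )
  data.frame(
    key     = vapply(L, `[[`, "", 1L),
    display = vapply(L, `[[`, "", 2L),
    default = as.numeric(vapply(L, `[[`, "", 3L)),
    nonneg  = as.logical(vapply(L, `[[`, "", 4L)),
    stringsAsFactors = FALSE
  )
}

.PARAM_TABLE <- .param_def()

#' Parameter name-mapping table
#'
#' Returns the table mapping each canonical snake_case parameter key to its
#' conventional published display name, default value and sign constraint.
#' Both spellings ("Thx"/"THx") and any capitalisation of the display name
#' are accepted wherever a parameter is addressed by name.
#'
#' @return A data frame with columns `key`, `display`, `default`, `nonneg`.
#' @export
#' @examples
#' head(param_table())
param_table <- function() .PARAM_TABLE

# fold a parameter name to a comparison form: lower case, runs of
# non-alphanumeric characters collapsed to single spaces
.fold_key <- function(x) {
  x <- tolower(x)
  x <- gsub("[^a-z0-9]+", " ", x)
  trimws(x)
}

.KEY_LOOKUP <- local({
  tab <- .PARAM_TABLE
  folded <- c(.fold_key(tab$key), .fold_key(tab$display))
  setNames(rep(tab$key, 2L), folded)
})

#' Normalise a parameter name to its canonical key
#'
#' Accepts canonical snake_case keys or published display names in any
#' capitalisation (e.g. `"Kill of CSC"`, `"kill_of_csc"`, `"CSC Thx dur"`).
#'
#' @param name Character vector of parameter names.
#' @return Character vector of canonical keys.
#' @export
normalize_param_key <- function(name) {
  stopifnot(is.character(name))
  folded <- .fold_key(name)
  key <- unname(.KEY_LOOKUP[folded])
  if (anyNA(key)) {
    bad <- name[is.na(key)]
    sug <- vapply(bad, function(b) {
      d <- adist(.fold_key(b), names(.KEY_LOOKUP))
      .KEY_LOOKUP[[which.min(d)]]
    }, "")
    stop("Unknown parameter name(s): ",
         paste0("'", bad, "' (did you mean '", sug, "'?)", collapse = ", "),
         call. = FALSE)
  }
  key
}

#' Default model parameters
#'
#' Constructs the full named parameter set at its published default values,
#' optionally replacing individual entries. Names in `...` or `overrides`
#' may use canonical keys or display names.
#'
#' @param ... Named scalar overrides.
#' @param overrides Optional named list/vector of overrides (merged after
#'   `...`).
#' @return A named numeric vector of class `hl_params` with one element per
#'   model constant.
#' @export
#' @examples
#' p <- default_parameters("Kill of CSC" = 0.1)
#' p[["kill_of_csc"]]
default_parameters <- function(..., overrides = NULL) {
  p <- setNames(.PARAM_TABLE$default, .PARAM_TABLE$key)
  class(p) <- "hl_params"
  ov <- c(list(...), as.list(overrides))
  if (length(ov)) p <- apply_overrides(p, ov)
  p
}

#' Apply named overrides to a parameter set
#'
#' @param base An `hl_params` vector (see [default_parameters()]).
#' @param overrides Named list or vector; names may be canonical keys or
#'   display names. Unknown names are an error (with a nearest-match
#'   suggestion).
#' @return A modified copy of `base`; the input is not changed.
#' @export
apply_overrides <- function(base, overrides) {
  stopifnot(inherits(base, "hl_params"))
  overrides <- as.list(overrides)
  if (!length(overrides)) return(base)
  if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
    stop("all overrides must be named", call. = FALSE)
  keys <- normalize_param_key(names(overrides))
  vals <- vapply(overrides, function(v) {
    v <- suppressWarnings(as.numeric(v))
    if (length(v) != 1L || is.na(v)) stop("override values must be single numbers",
                                          call. = FALSE)
    v
  }, numeric(1))
  base[keys] <- vals
  validate_parameters(base)
  base
}

#' Validate a parameter set
#'
#' Checks completeness, finiteness and sign constraints: capacities, death,
#' growth and differentiation rates, stimulation and killing couplings,
#' pulse start times and durations must be non-negative; pulse intensities
#' are unrestricted in sign (a negative intensity models a cell influx).
#'
#' @param params An `hl_params` vector.
#' @return Invisibly, `params` (errors on violation).
#' @export
validate_parameters <- function(params) {
  tab <- .PARAM_TABLE
  if (!all(tab$key %in% names(params)))
    stop("parameter set is missing: ",
         paste(setdiff(tab$key, names(params)), collapse = ", "), call. = FALSE)
  v <- unclass(params)[tab$key]
  bad <- !is.finite(v)
  if (any(bad))
    stop("non-finite parameter value: ", paste(tab$key[bad], collapse = ", "),
         call. = FALSE)
  neg <- tab$nonneg & v < 0
  if (any(neg))
    stop("negative value not allowed for: ",
         paste(tab$key[neg], collapse = ", "), call. = FALSE)
  invisible(params)
}

#' @export
print.hl_params <- function(x, ...) {
  cat("<hl_params> ", length(x), " model constants\n", sep = "")
  tab <- .PARAM_TABLE
  changed <- which(unclass(x)[tab$key] != tab$default)
  if (length(changed)) {
    cat("non-default entries:\n")
    for (i in changed)
      cat(sprintf("  %-24s %s  (default %s)\n", tab$key[i],
                  format(x[[tab$key[i]]]), format(tab$default[i])))
  } else {
    cat("all entries at default values\n")
  }
  invisible(x)
}
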