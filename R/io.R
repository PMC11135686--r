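# Table schemas: required columns (and their types) for each dataset kind
# the package reads or writes.
.TABLE_SCHEMAS <- list(
  timecourse = c(dose_nM = "numeric", time_min = "numeric",
                 observable = "character", value = "numeric",
                 sd = "numeric"),
  species_timecourse = c(t = "numeric"),  # plus one column per species
  dose_response = c(receptor_fc = "numeric", response_fc = "numeric",
                    replicate = "integer"),
  per_cell = c(cell_id = "integer", R1_0 = "numeric", R2_0 = "numeric",
               S2_0 = "numeric", k_NFR = "numeric"),
  scan = c(r1_mult = "numeric", r2_mult = "numeric", s2_mult = "numeric",
           rel_psmad2 = "numeric", n2c_fc = "numeric"),
  minimal_scan = c(R1tot = "numeric", R2tot = "numeric", Sa = "numeric"),
  profile = c(param = "character", value = "numeric",
              objective = "numeric")
)

#' Write / read a typed results table
#'
#' Tables are comma-separated UTF-8 text with a header row and a leading
#' `# schema: <name>` comment recording the table kind; numeric columns are
#' written with 17 significant digits so write-then-read round-trips
#' bit-identically.
#'
#' @param x data.frame to write.
#' @param path file path.
#' @param schema one of `timecourse`, `species_timecourse`, `dose_response`,
#'   `per_cell`, `scan`, `minimal_scan`, `profile`.
#' @return `write_table`: the path, invisibly.  `read_table`: the typed
#'   data.frame.
#' @export
write_table <- function(x, path, schema) {
  schema <- match.arg(schema, names(.TABLE_SCHEMAS))
  check_schema(x, schema)
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste0("# schema: ", schema), con)
  utils::write.table(format_table_num(x), con, sep = ",", row.names = FALSE,
                     quote = FALSE, qmethod = "double")
  invisible(path)
}

format_table_num <- function(x) {
  for (nm in names(x))
    if (is.double(x[[nm]]))
      x[[nm]] <- formatC(x[[nm]], digits = 17, format = "g")
  x
}

#' @param path file path.
#' @rdname write_table
#' @export
read_table <- function(path, schema) {
  schema <- match.arg(schema, names(.TABLE_SCHEMAS))
  first <- readLines(path, n = 1)
  declared <- sub("^# schema: *", "", first)
  if (startsWith(first, "# schema:") && declared != schema)
    stop(sprintf("schema mismatch: file declares '%s', requested '%s'",
                 declared, schema), call. = FALSE)
  x <- utils::read.csv(path, comment.char = "#",
                       stringsAsFactors = FALSE)
  check_schema(x, schema)
  want <- .TABLE_SCHEMAS[[schema]]
  for (nm in names(want)) {
    x[[nm]] <- switch(want[[nm]],
                      numeric = as.numeric(x[[nm]]),
                      integer = as.integer(x[[nm]]),
                      character = as.character(x[[nm]]))
  }
  x
}

check_schema <- function(x, schema) {
  want <- names(.TABLE_SCHEMAS[[schema]])
  missing <- setdiff(want, names(x))
  if (length(missing))
    stop(sprintf("schema '%s': missing required column(s): %s", schema,
                 paste(missing, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Load / save a run configuration
#'
#' Configurations are flat JSON objects.  `load_config` validates against
#' the known keys (unknown keys are rejected, names of offending keys
#' reported), fills defaults, and checks that rate constants are
#' non-negative.  `save_config` followed by `load_config` is the identity
#' on the defaulted configuration.
#'
#' @param path JSON file path.
#' @return A `run_config` list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path,
                               call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  as_run_config(raw)
}

default_config <- function() {
  list(preset = "hacat_like", overrides = list(), seed = 1L,
       dose_pM = 100, t_eval_min = 60,
       scan = list(n = 2000, decades_r = 5, decades_s = 2),
       single_cell = list(n_cells = 300, cv = 0.1, mult_r1 = 1, mult_r2 = 1,
                          tie_receptors = FALSE, times_min = c(60, 480)),
       fit = list(n_starts = 20, free = c("ka", "k_NFR", "kphos", "kdephos",
                                          "kin", "kex", "kin_p", "kr",
                                          "med_scale")),
       out_dir = ".")
}

as_run_config <- function(raw) {
  def <- default_config()
  bad <- setdiff(names(raw), names(def))
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  cfg <- utils::modifyList(def, raw, keep.null = TRUE)
  if (length(cfg$overrides)) {
    known <- names(.hacat_like_defaults())
    badov <- setdiff(names(cfg$overrides), known)
    if (length(badov))
      stop("unknown override key(s): ", paste(badov, collapse = ", "),
           call. = FALSE)
    neg <- names(cfg$overrides)[vapply(cfg$overrides,
                                       function(v) is.numeric(v) && v < 0,
                                       logical(1))]
    if (length(neg))
      stop("negative rate constant(s) in overrides: ",
           paste(neg, collapse = ", "), call. = FALSE)
  }
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "run_config")
}

#' @param cfg a `run_config` list.
#' @rdname load_config
#' @export
save_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Write a reproducibility manifest next to an output
#'
#' Records the config (inline and as an md5 hash), the seed and the package
#' version, so any output can be regenerated from its manifest alone.
#'
#' @param cfg the `run_config` used.
#' @param out_dir output directory.
#' @param command the subcommand that produced the outputs.
#' @return Path of the manifest file, invisibly.
#' @export
write_manifest <- function(cfg, out_dir, command) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(cfg, tmp)
  manifest <- list(
    command = command,
    config = unclass(cfg),
    config_md5 = unname(tools::md5sum(tmp)),
    seed = cfg$seed,
    package_version = as.character(utils::packageVersion("liebigsmad")),
    r_version = R.version.string
  )
  path <- file.path(out_dir, paste0("manifest-", command, ".json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
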