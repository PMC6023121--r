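#' Default dataset schema
#'
#' Required columns (with block tags for the environment table) for the three
#' CSV inputs of the pipeline. Units follow the field conventions: mm and
#' degrees Celsius for climate, percent / uS cm-1 / cmol+ kg-1 for soil,
#' m / ha / degrees / L s-1 for physical variables, percent cover and Simpson
#' 1-D for responses.
#'
#' @return List with `environment` (named block vector), `responses`
#'   (column names) and `traits` (column names).
#' @export
dataset_schema <- function() {
  tg <- env_marginal_targets()
  env_blocks <- stats::setNames(tg$block, tg$variable)
  env_blocks <- c(env_blocks, PP_PET = "climate", IDM = "climate",
                  Q2 = "climate", CN = "soil")
  list(
    environment = env_blocks,
    responses = c(paste0("cover_", c("GG", "ES", "ET", "DS", "DT")),
                  "cover_total_canopy",
                  paste0("div_", c("GG", "ES", "ET", "DS", "DT")), "div_total"),
    traits = c("species", "pft", "SLA", "toughness", "N_mass", "CN",
               "lignin", "Si")
  )
}

read_validated_csv <- function(path, required, numeric_cols, what,
                               blocks = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, comment.char = "#")
  problems <- character(0)
  miss <- setdiff(required, names(df))
  if (length(miss)) {
    lab <- if (!is.null(blocks))
      sprintf("%s (%s block)", miss, blocks[miss]) else miss
    problems <- c(problems, paste("missing column(s):", paste(lab, collapse = ", ")))
  }
  for (cc in intersect(numeric_cols, names(df))) {
    if (!is.numeric(df[[cc]]))
      problems <- c(problems, paste0("non-numeric values in column '", cc, "'"))
  }
  if ("site" %in% names(df) && anyDuplicated(df$site))
    problems <- c(problems,
                  paste("duplicate site id(s):",
                        paste(unique(df$site[duplicated(df$site)]), collapse = ", ")))
  if ("species" %in% names(df) && anyDuplicated(df$species))
    problems <- c(problems, "duplicate species id(s)")
  if (length(problems))
    stop("invalid ", what, " table (", path, "): ",
         paste(problems, collapse = "; "))
  df
}

#' Read a schema-validated environment table
#'
#' Reads a site-by-predictor CSV, validates it in one pass (all violations
#' reported together: missing columns with their block, non-numeric cells,
#' duplicate site ids) and attaches the block tags from the schema.
#'
#' @param path CSV path (comment lines starting with `#` are ignored).
#' @param schema A [dataset_schema()].
#' @return An environment table (see [as_environment_table()]).
#' @export
read_environment <- function(path, schema = dataset_schema()) {
  blocks <- schema$environment
  df <- read_validated_csv(path, c("site", names(blocks)), names(blocks),
                           "environment", blocks = blocks)
  as_environment_table(df[c("site", names(blocks))], blocks)
}

#' @rdname read_environment
#' @export
read_responses <- function(path, schema = dataset_schema()) {
  read_validated_csv(path, c("site", schema$responses), schema$responses,
                     "responses")
}

#' @rdname read_environment
#' @export
read_traits <- function(path, schema = dataset_schema()) {
  read_validated_csv(path, schema$traits, setdiff(schema$traits,
                                                  c("species", "pft")),
                     "traits")
}

#' Write the three tables of a dataset as CSV
#'
#' @param dataset A `"synthetic_dataset"` (or compatible list).
#' @param dir Output directory (created if absent).
#' @return Invisibly, the written paths.
#' @export
write_dataset_csv <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(environment = file.path(dir, "environment.csv"),
             responses = file.path(dir, "responses.csv"),
             traits = file.path(dir, "traits.csv"))
  utils::write.csv(as.data.frame(dataset$environment), paths["environment"],
                   row.names = FALSE)
  utils::write.csv(dataset$responses, paths["responses"], row.names = FALSE)
  utils::write.csv(dataset$traits, paths["traits"], row.names = FALSE)
  invisible(paths)
}

write_csv_with_header <- function(df, path, meta) {
  con <- file(path, open = "wb")  # binary: byte-identical across platforms
  on.exit(close(con))
  writeLines(paste0("# ", names(meta), ": ", unlist(meta)), con, sep = "\n")
  utils::write.csv(df, con, row.names = FALSE)
}

#' Write a pipeline report bundle to disk
#'
#' Emits deterministic CSV files (fixed column order and row sort, seeded
#' metadata embedded as `#` header comments, no timestamps): the
#' combination-model table, the univariate summary, the VIP report, the
#' trait-stage tables, the pruning removal log and the LNO partition.
#' Identical bundles produce byte-identical files. An empty VIP report
#' yields a header-only file.
#'
#' @param report A `"pls_report"` from [run_pipeline()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, the written file paths.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  meta <- list(
    package = "riparianPLS",
    seed = report$seed,
    q2_threshold = report$config$q2_threshold,
    n_groups = report$config$n_groups,
    sd_convention = "sample (n-1)",
    lno_eval = report$config$lno_eval,
    partition = paste(report$partition, collapse = " ")
  )
  combo <- rbind(cbind(response_set = "cover", report$combination$cover),
                 cbind(response_set = "diversity", report$combination$diversity))
  files <- c(
    combos = file.path(out_dir, "combination_models.csv"),
    univariate = file.path(out_dir, "univariate_models.csv"),
    vip = file.path(out_dir, "vip_report.csv"),
    anova = file.path(out_dir, "trait_anova.csv"),
    kmeans = file.path(out_dir, "kmeans_elbow.csv"),
    removals = file.path(out_dir, "pruning_removals.csv"),
    letters = file.path(out_dir, "tukey_letters.csv")
  )
  write_csv_with_header(combo, files["combos"], meta)
  write_csv_with_header(report$univariate$summary, files["univariate"], meta)
  write_csv_with_header(report$univariate$vip_report, files["vip"], meta)
  write_csv_with_header(report$traits$anova, files["anova"], meta)
  write_csv_with_header(report$traits$kmeans$per_k, files["kmeans"], meta)
  write_csv_with_header(report$pruning$removed, files["removals"], meta)
  letters_df <- do.call(rbind, lapply(names(report$traits$tukey), function(tr) {
    lt <- report$traits$tukey[[tr]]$letters
    data.frame(trait = tr, pft = names(lt), letters = unname(lt))
  }))
  write_csv_with_header(letters_df, files["letters"], meta)
  invisible(files)
}
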