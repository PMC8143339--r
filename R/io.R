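# Plain-text I/O: comma-separated observation tables (UTF-8, "." decimal,
# header required) and YAML parameter configurations. Times are stored
# relative to the drug dose; sampling schedules labelled "post-ConA" must be
# converted on ingest, matching the model equations' clock.

#' @keywords internal
.analyte_aliases <- c(
  "GRMS55" = "GRMS55", "GRMS-55" = "GRMS55", "DRUG" = "GRMS55",
  "TNFA" = "TNFa", "TNF-A" = "TNFa", "TNF-ALPHA" = "TNFa", "TNF" = "TNFa",
  "IFNG" = "IFNg", "IFN-G" = "IFNg", "IFN-GAMMA" = "IFNg", "IFN" = "IFNg",
  "IL6" = "IL6", "IL-6" = "IL6",
  "IL10" = "IL10", "IL-10" = "IL10",
  "ALT" = "ALT", "AST" = "AST")

#' Validate (and normalise) an observation table
#'
#' Checks the schema used throughout the package: columns `group`,
#' `animal_id`, `dose_mg_per_kg`, `time_h` (or `time_min`, auto-converted),
#' `analyte`, `value`, `unit`; analyte names are normalised to the canonical
#' set `GRMS55, TNFa, IFNg, IL6, IL10, ALT, AST`; values must be nonnegative
#' (zero permitted only for the drug analyte in unexposed animals); a given
#' animal may contribute at most one time point per analyte (destructive
#' sampling). An optional logical column `cona` marks whether the animal was
#' challenged; if absent it defaults to `TRUE` except for the `healthy`
#' group.
#'
#' @param data a data frame.
#' @return the validated data frame with canonical analyte names and a
#'   `cona` column.
#' @export
validate_observation_table <- function(data) {
  required <- c("group", "animal_id", "dose_mg_per_kg", "analyte", "value",
                "unit")
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols))
    stop("observation table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!"time_h" %in% names(data)) {
    if ("time_min" %in% names(data)) {
      data$time_h <- data$time_min / 60
      data$time_min <- NULL
    } else stop("observation table lacks column(s): time_h", call. = FALSE)
  }
  key <- toupper(trimws(as.character(data$analyte)))
  unknown <- which(!key %in% names(.analyte_aliases))
  if (length(unknown))
    stop(sprintf("unknown analyte '%s' in row %d", data$analyte[unknown[1]],
                 unknown[1]), call. = FALSE)
  data$analyte <- unname(.analyte_aliases[key])
  bad <- which(!is.finite(data$value) | data$value < 0 |
                 (data$value == 0 & data$analyte != "GRMS55"))
  if (length(bad))
    stop(sprintf("nonpositive or non-finite value in row %d", bad[1]),
         call. = FALSE)
  if (!"cona" %in% names(data))
    data$cona <- data$group != "healthy"
  dup <- duplicated(data[, c("animal_id", "analyte")])
  if (any(dup))
    stop(sprintf("duplicate (animal, analyte) record in row %d: %s/%s",
                 which(dup)[1], data$animal_id[which(dup)[1]],
                 data$analyte[which(dup)[1]]), call. = FALSE)
  data
}

#' Read an observation table from CSV
#'
#' @param path path to a comma-separated file with the schema described in
#'   [validate_observation_table()].
#' @return validated observation table.
#' @export
read_observation_table <- function(path) {
  validate_observation_table(read.csv(path, stringsAsFactors = FALSE))
}

#' Write an observation table to CSV
#'
#' @param data an observation table.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_observation_table <- function(data, path) {
  write.csv(validate_observation_table(data), path, row.names = FALSE,
            quote = FALSE)
  invisible(path)
}

#' Read a model parameter configuration
#'
#' Reads a YAML (or JSON) configuration with one key per model symbol,
#' grouped as `pk: {Vd_F, ka, ke}`, `tau`, `tnf/ifn/il6: {IC50, S, kout}`,
#' `il10: {S, kout, kin_dis, I_ifn}`, `disease: {S_ALT_TNF, S_ALT_IFN,
#' kout_ALT, S_AST_TNF, S_AST_IFN, kout_AST, alpha, beta}`, `baselines:
#' {TNFa, IFNg, IL6, IL10, ALT, AST}` and `conA_time`. The exponents `alpha`
#' and `beta` default to their fixed value 1.5 when omitted. Baselines are
#' required inputs (they are study-specific and not part of the published
#' parameter table): a configuration without them fails with an explicit
#' error unless they are passed through `baselines`.
#'
#' @param path path to the configuration file.
#' @param baselines optional named vector overriding/supplying the baselines.
#' @return a [model_parameters()] object.
#' @export
read_parameters <- function(path, baselines = NULL) {
  cfg <- yaml::read_yaml(path)
  need <- function(block, keys, where) {
    if (is.null(block))
      stop("parameter config lacks section '", where, "'", call. = FALSE)
    miss <- setdiff(keys, names(block))
    if (length(miss))
      stop("parameter config lacks key(s) in '", where, "': ",
           paste(miss, collapse = ", "), call. = FALSE)
    for (k in keys)
      if (!is.numeric(block[[k]]))
        stop("parameter '", where, ".", k, "' must be numeric", call. = FALSE)
    block
  }
  pkc <- need(cfg$pk, c("Vd_F", "ka", "ke"), "pk")
  if (is.null(cfg$tau)) stop("parameter config lacks 'tau'", call. = FALSE)
  b <- cfg$baselines
  if (!is.null(baselines)) b <- modifyList(if (is.null(b)) list() else b,
                                           as.list(baselines))
  bk <- c("TNFa", "IFNg", "IL6", "IL10", "ALT", "AST")
  if (is.null(b) || !all(bk %in% names(b)))
    stop("baselines (R0) are required: supply 'baselines' with keys ",
         paste(bk, collapse = ", "),
         " in the config or via the 'baselines' argument", call. = FALSE)
  cyt <- function(nm) {
    cc <- need(cfg[[nm]], c("IC50", "S", "kout"), nm)
    cytokine_parameters(nm, IC50 = cc$IC50, S = cc$S, kout = cc$kout,
                        R0 = b[[c(tnf = "TNFa", ifn = "IFNg",
                                  il6 = "IL6")[[nm]]]],
                        Imax = if (is.null(cc$Imax)) 1 else cc$Imax)
  }
  il10c <- need(cfg$il10, c("S", "kout", "kin_dis", "I_ifn"), "il10")
  dc <- need(cfg$disease, c("S_ALT_TNF", "S_ALT_IFN", "kout_ALT",
                            "S_AST_TNF", "S_AST_IFN", "kout_AST"), "disease")
  model_parameters(
    pk = pk_parameters(pkc$Vd_F, pkc$ka, pkc$ke),
    tau = cfg$tau,
    tnf = cyt("tnf"), ifn = cyt("ifn"), il6 = cyt("il6"),
    il10 = il10_parameters(S = il10c$S, kout = il10c$kout,
                           kin_dis = il10c$kin_dis, I_ifn = il10c$I_ifn,
                           R0 = b[["IL10"]]),
    disease = disease_parameters(
      S_ALT_TNF = dc$S_ALT_TNF, S_ALT_IFN = dc$S_ALT_IFN,
      kout_ALT = dc$kout_ALT, S_AST_TNF = dc$S_AST_TNF,
      S_AST_IFN = dc$S_AST_IFN, kout_AST = dc$kout_AST,
      R0_ALT = b[["ALT"]], R0_AST = b[["AST"]],
      alpha = if (is.null(dc$alpha)) 1.5 else dc$alpha,
      beta = if (is.null(dc$beta)) 1.5 else dc$beta),
    conA_time = if (is.null(cfg$conA_time)) 0.5 else cfg$conA_time)
}

#' Write a model parameter configuration
#'
#' Serialises a parameter set to YAML in the layout read by
#' [read_parameters()].
#'
#' @param params a [model_parameters()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "cona_parameters"))
  cfg <- list(
    pk = list(Vd_F = params$pk$Vd_F, ka = params$pk$ka, ke = params$pk$ke),
    tau = params$tau,
    tnf = list(IC50 = params$tnf$IC50, S = params$tnf$S,
               kout = params$tnf$kout, Imax = params$tnf$Imax),
    ifn = list(IC50 = params$ifn$IC50, S = params$ifn$S,
               kout = params$ifn$kout, Imax = params$ifn$Imax),
    il6 = list(IC50 = params$il6$IC50, S = params$il6$S,
               kout = params$il6$kout, Imax = params$il6$Imax),
    il10 = list(S = params$il10$S, kout = params$il10$kout,
                kin_dis = params$il10$kin_dis, I_ifn = params$il10$I_ifn),
    disease = list(S_ALT_TNF = params$disease$S_ALT_TNF,
                   S_ALT_IFN = params$disease$S_ALT_IFN,
                   kout_ALT = params$disease$kout_ALT,
                   S_AST_TNF = params$disease$S_AST_TNF,
                   S_AST_IFN = params$disease$S_AST_IFN,
                   kout_AST = params$disease$kout_AST,
                   alpha = params$disease$alpha, beta = params$disease$beta),
    baselines = list(TNFa = params$tnf$R0, IFNg = params$ifn$R0,
                     IL6 = params$il6$R0, IL10 = params$il10$R0,
                     ALT = params$disease$R0_ALT, AST = params$disease$R0_AST),
    conA_time = params$conA_time)
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Serialise a fit result to JSON
#'
#' @param fit a `cona_fit` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fit_result <- function(fit, path) {
  stopifnot(inherits(fit, "cona_fit"))
  out <- list(schema = "conahep-fit/1",
              estimates = as.list(fit$estimates),
              cv_percent = as.list(fit$cv_percent),
              objective = fit$objective, aic = fit$aic, bic = fit$bic,
              n_obs = fit$n_obs, converged = fit$converged,
              fixed = fit$fixed, unidentifiable = fit$unidentifiable,
              message = fit$message)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
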