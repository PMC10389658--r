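# Linguistic data model: per-language phonological parameters and the
# derived consonant-heaviness family of indices.

TONE_CATEGORIES <- c("None", "Marginal", "Simple", "ModeratelyComplex", "Complex")
GLOTC_LEVELS <- c("No", "Ej", "Imp", "Res", "Ej & Imp", "Ej & Res",
                  "Ej Imp & Res", "Imp & Res", "Plosives")
NV_LEVELS <- c("None", "Some", "All")
VLENGTH_LEVELS <- c("None", "Some", "All", "Other")

# internal column name -> CSV header (Table-1 parameter names)
LANGUAGE_CSV_COLUMNS <- c(
  id = "id", name = "name", lon = "lon", lat = "lat", stable = "stable",
  onset = "Onset", coda = "Coda", vq = "VQ", vtotal = "VTotal",
  vow_index = "VowIndex", ctotal = "CTotal", obstr = "Obstr",
  seg_tot = "SegTot", cplus_vq = "CplusVQ", obs_pct = "ObsPct",
  tone_cat = "ToneCat", tone_ordinal = "ToneOrdinal", ons_coda = "OnsCoda",
  cons_heavy = "ConsHeavy", cheavy_obstr = "CHeavyObstr",
  cheavy_log = "CHeavyLog", obs_lat = "ObsLat", f_rnd_v = "FRndV",
  glot_c = "GlotC", ejectives = "Ejectives", n_ejectives = "#Ejectives",
  implosives = "Implosives", n_implosives = "#Implosives",
  glot_res = "GlotRes", n_glot_res = "#GlotRes", velar_nas = "VelarNas",
  nv_pattern = "NVPattern", pnc = "PNC's", vlength = "VLength",
  aspirates = "Aspirates"
)

check_index_range <- function(x, name, lo, hi, integer = TRUE) {
  bad <- !is.finite(x) | x < lo | x > hi | (integer & x != round(x))
  if (any(bad)) {
    stop(sprintf("%s out of range [%d, %d]: %s", name, lo, hi,
                 paste(utils::head(x[bad], 5), collapse = ", ")), call. = FALSE)
  }
  invisible(x)
}

#' Maximum onset-plus-coda complexity
#'
#' Sum of the onset and coda complexity indices, each graded 0-3, giving a
#' syllable-complexity score in 0-6.
#'
#' @param onset,coda integer complexity indices in 0-3.
#' @return integer vector in 0-6.
#' @export
compute_ons_coda <- function(onset, coda) {
  check_index_range(onset, "onset", 0, 3)
  check_index_range(coda, "coda", 0, 3)
  as.integer(onset + coda)
}

#' Consonant heaviness index
#'
#' `OnsCoda + CTotal / 4`: combines maximal syllable-margin complexity with
#' the size of the consonant inventory.
#'
#' @param ons_coda integer in 0-6 (see [compute_ons_coda()]).
#' @param ctotal consonant inventory size, at least 1.
#' @return numeric vector.
#' @export
compute_cons_heavy <- function(ons_coda, ctotal) {
  check_index_range(ons_coda, "ons_coda", 0, 6)
  if (any(!is.finite(ctotal) | ctotal < 1 | ctotal != round(ctotal))) {
    stop("ctotal must be an integer count >= 1", call. = FALSE)
  }
  ons_coda + ctotal / 4
}

#' Obstruent-based consonant heaviness index
#'
#' `OnsCoda + Obstr / 3`, using only the obstruent portion of the consonant
#' inventory.
#'
#' @param ons_coda integer in 0-6.
#' @param obstr obstruent count, non-negative integer.
#' @return numeric vector.
#' @export
compute_cheavy_obstr <- function(ons_coda, obstr) {
  check_index_range(ons_coda, "ons_coda", 0, 6)
  if (any(!is.finite(obstr) | obstr < 0 | obstr != round(obstr))) {
    stop("obstr must be an integer count >= 0", call. = FALSE)
  }
  ons_coda + obstr / 3
}

#' Log-based consonant heaviness index
#'
#' `OnsCoda + log(CTotal)` with the natural logarithm, damping the influence
#' of very large consonant inventories.
#'
#' @inheritParams compute_cons_heavy
#' @return numeric vector.
#' @export
compute_cheavy_log <- function(ons_coda, ctotal) {
  check_index_range(ons_coda, "ons_coda", 0, 6)
  if (any(!is.finite(ctotal) | ctotal < 1 | ctotal != round(ctotal))) {
    stop("ctotal must be an integer count >= 1", call. = FALSE)
  }
  ons_coda + log(ctotal)
}

#' Percentage of obstruents in the consonant inventory
#'
#' @param obstr obstruent count, `0 <= obstr <= ctotal`.
#' @param ctotal consonant inventory size, at least 1.
#' @return percentage in `[0, 100]`.
#' @export
compute_obs_pct <- function(obstr, ctotal) {
  if (any(!is.finite(ctotal) | ctotal < 1)) stop("ctotal must be >= 1", call. = FALSE)
  if (any(!is.finite(obstr) | obstr < 0)) stop("obstr must be >= 0", call. = FALSE)
  if (any(obstr > ctotal)) stop("obstr may not exceed ctotal", call. = FALSE)
  100 * obstr / ctotal
}

#' Wordlist vowel index
#'
#' The proportion of vowel symbols among all classifiable symbols in a short
#' standardized wordlist transcription.  Word boundaries are ignored; length
#' marks are stripped before counting (the source transcription convention
#' ignores vowel length).  Symbols in neither the vowel nor the consonant set
#' are reported via a warning and excluded.
#'
#' @param wordlist character vector of transcribed words.
#' @param vowels character vector of symbols counted as vowels.
#' @param consonants optional character vector of consonant symbols; if
#'   `NULL`, every non-vowel symbol counts as a consonant.
#' @param length_marks symbols stripped before counting (default the IPA
#'   length marks and the colon).
#' @return the vowel index, a real number in `[0, 1]`.
#' @export
compute_vowel_index <- function(wordlist, vowels, consonants = NULL,
                                length_marks = c("ː", "ˑ", ":")) {
  if (length(wordlist) == 0L || all(!nzchar(wordlist))) {
    stop("wordlist is empty", call. = FALSE)
  }
  syms <- unlist(strsplit(wordlist, "", fixed = TRUE))
  syms <- syms[!syms %in% c(length_marks, " ", "-")]
  is_v <- syms %in% vowels
  if (is.null(consonants)) {
    is_c <- !is_v
  } else {
    is_c <- syms %in% consonants & !is_v
    unclass <- unique(syms[!is_v & !is_c])
    if (length(unclass) > 0L) {
      warning("unclassifiable symbols excluded: ",
              paste(unclass, collapse = " "), call. = FALSE)
    }
  }
  total <- sum(is_v) + sum(is_c)
  if (total == 0L) stop("no classifiable symbols in wordlist", call. = FALSE)
  sum(is_v) / total
}

#' Map a tone-system category to its ordinal complexity rank
#'
#' `None` maps to 0; `Marginal` and `Simple` to 1; `ModeratelyComplex` to 2;
#' `Complex` (more than 3 tones) to 3.
#'
#' @param tone_cat character vector of tone categories (spaces in labels are
#'   tolerated, e.g. `"Moderately Complex"`).
#' @return integer vector in 0-3.
#' @export
map_tone_ordinal <- function(tone_cat) {
  key <- gsub("[ _]", "", as.character(tone_cat))
  map <- c(None = 0L, Marginal = 1L, Simple = 1L,
           ModeratelyComplex = 2L, Complex = 3L)
  bad <- !key %in% names(map)
  if (any(bad)) {
    stop("unknown tone category: ", paste(unique(tone_cat[bad]), collapse = ", "),
         call. = FALSE)
  }
  unname(map[key])
}

#' Recompute all derived indices of a language table
#'
#' Derived columns (`ons_coda`, `cons_heavy`, `cheavy_obstr`, `cheavy_log`,
#' `obs_pct`, `seg_tot`, `cplus_vq`, `tone_ordinal`) are recomputed from the
#' primitive fields; recomputed values are authoritative.
#'
#' @param df language table with primitive columns `onset`, `coda`, `ctotal`,
#'   `obstr`, `vq`, `vtotal`, `tone_cat`.
#' @return `df` with derived columns filled in.
#' @export
add_derived_indices <- function(df) {
  df$ons_coda <- compute_ons_coda(df$onset, df$coda)
  df$cons_heavy <- compute_cons_heavy(df$ons_coda, df$ctotal)
  df$cheavy_obstr <- compute_cheavy_obstr(df$ons_coda, df$obstr)
  df$cheavy_log <- compute_cheavy_log(df$ons_coda, df$ctotal)
  df$obs_pct <- compute_obs_pct(df$obstr, df$ctotal)
  df$seg_tot <- as.integer(df$vtotal + df$ctotal)
  df$cplus_vq <- as.integer(df$vq + df$ctotal)
  df$tone_ordinal <- map_tone_ordinal(df$tone_cat)
  df
}

#' Validate a language table against the data-model invariants
#'
#' @param df language table (internal column names).
#' @return character vector of problems; empty if the table is valid.
#' @export
validate_language_table <- function(df) {
  problems <- character(0)
  note <- function(rows, msg) {
    if (length(rows) > 0) {
      problems <<- c(problems, sprintf("rows %s: %s",
                                       paste(utils::head(rows, 10), collapse = ","), msg))
    }
  }
  note(which(duplicated(df$id)), "duplicate id")
  note(which(df$lon < -180 | df$lon > 180 | is.na(df$lon)), "lon outside [-180, 180]")
  note(which(df$lat < -90 | df$lat > 90 | is.na(df$lat)), "lat outside [-90, 90]")
  note(which(df$onset < 0 | df$onset > 3), "onset outside 0-3")
  note(which(df$coda < 0 | df$coda > 3), "coda outside 0-3")
  note(which(df$ctotal < 1), "ctotal < 1")
  note(which(df$obstr < 0), "negative obstr")
  note(which(df$obstr > df$ctotal), "obstr > ctotal")
  note(which(df$vq < 2 | df$vq > 20), "vq outside 2-20")
  note(which(df$vq > df$vtotal), "vq > vtotal")
  note(which(!df$tone_cat %in% TONE_CATEGORIES &
               !gsub(" ", "", df$tone_cat) %in% TONE_CATEGORIES), "unknown tone_cat")
  note(which(df$ejectives != (df$n_ejectives >= 1)), "ejectives flag/count mismatch")
  note(which(df$implosives != (df$n_implosives >= 1)), "implosives flag/count mismatch")
  note(which(df$glot_res != (df$n_glot_res >= 1)), "glot_res flag/count mismatch")
  if (!is.null(df$vow_index)) {
    note(which(!is.na(df$vow_index) & (df$vow_index <= 0 | df$vow_index >= 1)),
         "vow_index outside (0, 1)")
  }
  problems
}

#' Read a language table from CSV
#'
#' Columns follow the Table-1 parameter names plus `id, name, lon, lat,
#' stable`.  Derived-index columns in the file are advisory: they are
#' recomputed from the primitive fields and mismatches beyond `1e-6` are
#' reported with a warning (the recomputed values win).  Hard invariant
#' violations (e.g. more obstruents than consonants) are errors.
#'
#' @param path CSV file, UTF-8, header row.
#' @return a tibble with internal column names, one row per language.
#' @export
read_language_csv <- function(path) {
  raw <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                         fileEncoding = "UTF-8")
  mandatory <- c("id", "name", "lon", "lat", "Onset", "Coda", "VQ", "VTotal",
                 "CTotal", "Obstr", "ToneCat")
  missing_cols <- setdiff(mandatory, names(raw))
  if (length(missing_cols) > 0) {
    stop("missing mandatory columns: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- tibble::tibble(.rows = nrow(raw))
  for (internal in names(LANGUAGE_CSV_COLUMNS)) {
    csv_name <- LANGUAGE_CSV_COLUMNS[[internal]]
    if (csv_name %in% names(raw)) df[[internal]] <- raw[[csv_name]]
  }
  if (!is.numeric(df$lon) || !is.numeric(df$lat)) {
    stop("unparseable coordinates", call. = FALSE)
  }
  for (col in c("stable", "obs_lat", "f_rnd_v", "ejectives", "implosives",
                "glot_res", "velar_nas", "pnc", "aspirates")) {
    if (!is.null(df[[col]])) df[[col]] <- parse_flag(df[[col]])
  }
  stored <- df[intersect(names(df), c("ons_coda", "cons_heavy", "cheavy_obstr",
                                      "cheavy_log", "obs_pct", "seg_tot",
                                      "cplus_vq", "tone_ordinal"))]
  problems <- validate_language_table(df)
  if (length(problems) > 0) {
    stop("invalid language table:\n  ", paste(problems, collapse = "\n  "),
         call. = FALSE)
  }
  df <- add_derived_indices(df)
  for (col in names(stored)) {
    delta <- abs(stored[[col]] - df[[col]])
    off <- which(!is.na(delta) & delta > 1e-6)
    if (length(off) > 0) {
      warning(sprintf("stored %s differs from recomputed value in %d row(s); recomputed values used",
                      col, length(off)), call. = FALSE)
    }
  }
  df
}

parse_flag <- function(x) {
  if (is.logical(x)) return(x)
  if (is.numeric(x)) return(x != 0)
  tolower(trimws(x)) %in% c("yes", "true", "y", "1")
}

#' Write a language table to CSV
#'
#' Inverse of [read_language_csv()]; round-trips losslessly.
#'
#' @param df language table (internal column names).
#' @param path output CSV file.
#' @export
write_language_csv <- function(df, path) {
  out <- df[intersect(names(LANGUAGE_CSV_COLUMNS), names(df))]
  names(out) <- LANGUAGE_CSV_COLUMNS[names(out)]
  utils::write.csv(out, path, row.names = FALSE, fileEncoding = "UTF-8", na = "")
  invisible(path)
}
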