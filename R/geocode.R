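# Fully offline two-step fuzzy geocoder against a building registry.
# Addresses are normalized (lowercase, diacritics and punctuation removed,
# abbreviations expanded, street number extracted), then matched by
# Ratcliff-Obershelp sequence similarity: a quick pass within the address's
# postal code, and a slow pass over the whole registry when the quick pass
# stays below the acceptance threshold. Streets matched without a usable
# street number fall back to the street centroid.

#' Default street-type abbreviation dictionary
#'
#' Keys are matched as whole tokens after lowercasing and diacritic
#' removal, with any trailing dot stripped. Extend by passing your own
#' named vector to [normalize_address()] / [geocode_addresses()].
#'
#' @export
default_abbreviations <- function() {
  c(ch = "chemin", av = "avenue", bd = "boulevard", r = "rue",
    rte = "route", pl = "place", imp = "impasse", prom = "promenade",
    st = "saint", ste = "sainte")
}

strip_diacritics <- function(s) {
  chartr("àâäéèêëîïôöùûüç",
         "aaaeeeeiioouuuc", s)
}

#' Normalize an address string
#'
#' Lowercases, removes diacritics and punctuation, expands street-type
#' abbreviations, and extracts the street number (the last token made of
#' digits optionally followed by letters, e.g. "12" or "12bis").
#'
#' @param raw address string(s)
#' @param abbreviations named character vector of token expansions
#' @return list with `name` (normalized street name, `NA` when nothing
#'   remains) and `number` (extracted street number or `NA`)
#' @export
normalize_address <- function(raw, abbreviations = default_abbreviations()) {
  assert_that(all(nzchar(raw)), "failed normalization: empty address string")
  s <- strip_diacritics(tolower(raw))
  s <- gsub("[^a-z0-9 ]", " ", gsub("\\.", ". ", s)) # dots end tokens
  toks <- strsplit(trimws(gsub(" +", " ", s)), " ", fixed = TRUE)
  out_name <- character(length(toks))
  out_num <- rep(NA_character_, length(toks))
  for (i in seq_along(toks)) {
    tk <- toks[[i]]
    is_num <- grepl("^[0-9]+[a-z]*$", tk)
    if (any(is_num)) {
      out_num[i] <- tk[max(which(is_num))]
      tk <- tk[!is_num]
    }
    hit <- match(tk, names(abbreviations))
    tk[!is.na(hit)] <- abbreviations[hit[!is.na(hit)]]
    out_name[i] <- if (length(tk)) paste(tk, collapse = " ") else NA_character_
  }
  list(name = out_name, number = out_num)
}

#' Ratcliff-Obershelp sequence similarity
#'
#' `2M / (|a| + |b|)` where `M` is the total number of characters in the
#' recursively found longest matching blocks. 1 for identical strings, 0
#' for strings with no characters in common.
#'
#' @param a,b character strings
#' @return ratio in `[0, 1]`
#' @export
seq_similarity <- function(a, b) {
  assert_that(nzchar(a) && nzchar(b), "similarity needs non-empty strings")
  rcpp_similarity(a, b)
}

#' Index a building registry for geocoding
#'
#' Normalizes street names and builds the per-street lookup used by
#' [geocode()]. Registry columns: `street_name`, `street_number`,
#' `postal_code`, `x`, `y`.
#'
#' @param registry data.frame of building records
#' @param abbreviations abbreviation dictionary
#' @return data.table keyed for matching, with `norm_street` and a
#'   deterministic `registry_key` = "norm_street|postal_code"
#' @export
prepare_registry <- function(registry, abbreviations = default_abbreviations()) {
  reg <- data.table::as.data.table(registry)
  assert_that(nrow(reg) > 0L, "configuration error: empty registry")
  nm <- normalize_address(reg$street_name, abbreviations)
  reg[, norm_street := nm$name]
  reg[, norm_number := tolower(trimws(as.character(street_number)))]
  reg[, postal_code := as.character(postal_code)]
  reg[, registry_key := paste(norm_street, postal_code, sep = "|")]
  data.table::setkey(reg, registry_key)
  reg
}

match_street <- function(name, streets, preferred_postal = NA_character_) {
  # streets: data.table with registry_key, norm_street, postal_code
  sims <- rcpp_similarity_many(name, streets$norm_street)
  best <- max(sims)
  # ties: prefer the address's postal code, then smallest registry key
  cand <- which(sims >= best - 1e-12)
  same_pc <- !is.na(preferred_postal) & streets$postal_code[cand] == preferred_postal
  pick <- cand[order(!same_pc, streets$registry_key[cand])][1]
  list(key = streets$registry_key[pick], similarity = best)
}

geocode_one <- function(name, number, postal, reg, streets, threshold) {
  if (is.na(name)) {
    return(list(x = NA_real_, y = NA_real_, similarity = NA_real_,
                method = "failed", matched_key = NA_character_))
  }
  method <- "quick"
  pool <- streets[streets$postal_code == postal, ]
  m <- if (!is.na(postal) && nrow(pool)) match_street(name, pool) else
    list(key = NA_character_, similarity = -Inf)
  if (m$similarity < threshold) { # slow pass: whole registry
    method <- "slow"
    m <- match_street(name, streets, preferred_postal = postal)
  }
  if (m$similarity < threshold) {
    return(list(x = NA_real_, y = NA_real_, similarity = m$similarity,
                method = "failed", matched_key = NA_character_))
  }
  entries <- reg[.(m$key)]
  if (!is.na(number)) {
    hit <- entries[entries$norm_number == tolower(number), ]
    if (nrow(hit)) {
      return(list(x = hit$x[1], y = hit$y[1], similarity = m$similarity,
                  method = method, matched_key = m$key))
    }
  }
  list(x = mean(entries$x), y = mean(entries$y), similarity = m$similarity,
       method = "street_centroid", matched_key = m$key)
}

#' Geocode one address against a prepared registry
#'
#' Quick pass searches streets sharing the postal code; if the best
#' similarity falls below `threshold` the slow pass searches the whole
#' registry. A matched street without a matching street number returns the
#' street centroid. Below threshold everywhere, the result is `failed`.
#'
#' @param address list/row with `raw` and optional `postal_code`
#' @param registry a [prepare_registry()] result (a raw data.frame is
#'   prepared on the fly)
#' @param threshold acceptance similarity threshold (default 0.80)
#' @param abbreviations abbreviation dictionary
#' @return list: x, y, similarity, method (`quick`/`slow`/
#'   `street_centroid`/`failed`), matched_key
#' @export
geocode <- function(address, registry, threshold = 0.80,
                    abbreviations = default_abbreviations()) {
  if (!"norm_street" %in% names(registry)) {
    registry <- prepare_registry(registry, abbreviations)
  }
  streets <- unique(registry[, .(registry_key, norm_street, postal_code)])
  nm <- normalize_address(address$raw, abbreviations)
  geocode_one(nm$name[1], nm$number[1],
              as.character(address$postal_code %||% NA_character_),
              registry, streets, threshold)
}

#' Geocode a table of addresses
#'
#' @param addresses data.frame with `raw` (address string) and optionally
#'   `postal_code`; an `id` column is carried through
#' @inheritParams geocode
#' @return data.table: id, x, y, similarity, method, matched_key
#' @export
geocode_addresses <- function(addresses, registry, threshold = 0.80,
                              abbreviations = default_abbreviations()) {
  addresses <- data.table::as.data.table(addresses)
  if (!"id" %in% names(addresses)) addresses[, id := .I]
  reg <- if ("norm_street" %in% names(registry)) registry else
    prepare_registry(registry, abbreviations)
  streets <- unique(reg[, .(registry_key, norm_street, postal_code)])
  nm <- normalize_address(addresses$raw, abbreviations)
  pc <- if ("postal_code" %in% names(addresses))
    as.character(addresses$postal_code) else rep(NA_character_, nrow(addresses))
  res <- vector("list", nrow(addresses))
  for (i in seq_len(nrow(addresses))) {
    res[[i]] <- geocode_one(nm$name[i], nm$number[i], pc[i], reg, streets,
                            threshold)
  }
  out <- data.table::rbindlist(res)
  out[, id := addresses$id]
  data.table::setcolorder(out, "id")
  out[]
}

#' Addresses in the manual-review similarity band
#'
#' Matches near the acceptance threshold (similarity in `[lo, hi]`), the
#' band a screening program would review by hand.
#'
#' @param geocoded a [geocode_addresses()] result
#' @param lo,hi band limits (defaults 0.75, 0.85)
#' @export
review_band <- function(geocoded, lo = 0.75, hi = 0.85) {
  geocoded[!is.na(similarity) & similarity >= lo & similarity <= hi]
}
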