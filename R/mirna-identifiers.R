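# miRBase-style nomenclature: [species prefix-]core[-arm], e.g. hsa-miR-301b-3p.
# A leading 3-4 letter token is only a species prefix when what follows starts
# with a known mature-miRNA core stem; this keeps "let-7a" from being split
# into prefix "let" + core "7a".
CORE_STEMS <- c("mir", "let", "lin", "bantam")

#' Matching policy for miRNA identifiers
#'
#' Controls how strictly two miRNA identifiers are compared and how they are
#' collapsed into cluster keys. Omitted components (species prefix, -3p/-5p
#' arm) always act as wildcards during matching; the policy flags additionally
#' let full identifiers ignore those components.
#'
#' @param ignore_species_prefix Drop the species prefix ("hsa", "mmu", ...)
#'   when matching and clustering.
#' @param cluster_arms Treat `-3p`, `-5p` and arm-less identifiers as one
#'   cluster.
#' @param case_insensitive_core Compare cores case-insensitively
#'   ("miR-1" == "mir-1"). Source databases mix capitalization, so this
#'   defaults to `TRUE`.
#'
#' @return An object of class `match_policy`.
#' @examples
#' match_policy()                       # default: strict prefix/arm, fold case
#' match_policy(cluster_arms = TRUE, ignore_species_prefix = TRUE)
#' @export
match_policy <- function(ignore_species_prefix = FALSE,
                         cluster_arms = FALSE,
                         case_insensitive_core = TRUE) {
  structure(
    list(
      ignore_species_prefix = isTRUE(ignore_species_prefix),
      cluster_arms = isTRUE(cluster_arms),
      case_insensitive_core = isTRUE(case_insensitive_core)
    ),
    class = "match_policy"
  )
}

#' @export
print.match_policy <- function(x, ...) {
  cat("<match_policy>",
      sprintf("  ignore_species_prefix: %s", x$ignore_species_prefix),
      sprintf("  cluster_arms:          %s", x$cluster_arms),
      sprintf("  case_insensitive_core: %s", x$case_insensitive_core),
      sep = "\n")
  invisible(x)
}

#' Parse miRNA identifiers
#'
#' Splits raw miRNA identifiers into species prefix, core name, and hairpin
#' arm. Full identifiers (`hsa-miR-301b-3p`) and shortened ones without prefix
#' and/or arm (`miR-301b-3p`, `hsa-miR-301b`, `miR-301b`) are all accepted.
#' Unparseable lines (empty core after stripping) are never an error: they are
#' dropped and reported via the `skipped` attribute, so arbitrary printable
#' input is safe.
#'
#' Trailing copy-number suffixes (`miR-302a-1`) stay part of the core; only a
#' literal trailing `-3p`/`-5p` is an arm.
#'
#' @param x Character vector of raw identifiers.
#'
#' @return A tibble with columns `raw`, `species_prefix`, `core`, `arm`
#'   (`NA` where absent) and `canonical` (prefix + core + arm re-joined with
#'   hyphens). Rejected inputs are recorded in `attr(, "skipped")`, a tibble
#'   with columns `raw` and `reason`.
#' @examples
#' parse_mirna_ids(c("hsa-miR-301b-3p", "miR-301b", "let-7a"))
#' @export
parse_mirna_ids <- function(x) {
  stopifnot(is.character(x))
  raw <- x
  s <- stringr::str_trim(x)

  prefix <- rep(NA_character_, length(s))
  arm <- rep(NA_character_, length(s))
  rest <- s

  # species prefix: 3-4 letters, hyphen, remainder starting with a core stem
  pm <- stringr::str_match(rest, "^([A-Za-z]{3,4})-(.+)$")
  stem_re <- paste0("^(", paste(CORE_STEMS, collapse = "|"), ")")
  has_prefix <- !is.na(pm[, 1]) &
    stringr::str_detect(tolower(pm[, 3]), stem_re)
  prefix[has_prefix] <- tolower(pm[has_prefix, 2])
  rest[has_prefix] <- pm[has_prefix, 3]

  am <- stringr::str_match(rest, "^(.*)-([35]p)$")
  has_arm <- !is.na(am[, 1])
  arm[has_arm] <- am[has_arm, 3]
  rest[has_arm] <- am[has_arm, 2]

  core <- rest
  ok <- !is.na(core) & nchar(core) > 0
  reason <- dplyr::case_when(
    is.na(s) | s == "" ~ "empty input",
    !ok ~ "empty core",
    TRUE ~ NA_character_
  )

  out <- tibble::tibble(
    raw = raw[ok],
    species_prefix = prefix[ok],
    core = core[ok],
    arm = arm[ok]
  )
  out$canonical <- mirna_canonical(out)

  skipped <- tibble::tibble(raw = raw[!ok], reason = reason[!ok])
  if (nrow(skipped) > 0) {
    rlang::warn(sprintf("Skipped %d unparseable miRNA identifier(s).",
                        nrow(skipped)))
  }
  attr(out, "skipped") <- skipped
  out
}

# canonical serialization of a parsed identifier tibble
mirna_canonical <- function(ids) {
  paste_na <- function(a, b) ifelse(is.na(a), b, paste(a, b, sep = "-"))
  paste_na(ids$species_prefix, ifelse(is.na(ids$arm), ids$core,
                                      paste(ids$core, ids$arm, sep = "-")))
}

#' Cluster key for a parsed miRNA identifier
#'
#' Collapses parsed identifiers into deterministic keys under a
#' [match_policy()]: the arm is stripped when `cluster_arms` is on, the
#' species prefix when `ignore_species_prefix` is on, and the result is
#' lower-cased when `case_insensitive_core` is on. Input identifiers sharing
#' a key form one cluster; duplicated keys are how shortened, more general
#' identifiers aggregate several full ones.
#'
#' @param ids Tibble from [parse_mirna_ids()] (columns `species_prefix`,
#'   `core`, `arm`).
#' @param policy A [match_policy()].
#'
#' @return Character vector of keys, one per row of `ids`.
#' @examples
#' ids <- parse_mirna_ids(c("hsa-miR-1-3p", "mmu-miR-1-5p"))
#' cluster_key(ids, match_policy(ignore_species_prefix = TRUE,
#'                               cluster_arms = TRUE))
#' @export
cluster_key <- function(ids, policy = match_policy()) {
  stopifnot(inherits(policy, "match_policy"))
  k <- ids
  if (policy$cluster_arms) k$arm <- NA_character_
  if (policy$ignore_species_prefix) k$species_prefix <- NA_character_
  key <- mirna_canonical(k)
  if (policy$case_insensitive_core) key <- tolower(key)
  key
}

#' Semantic comparison of miRNA identifiers
#'
#' Two identifiers match when their cores agree (case per policy) and the
#' species prefix and arm are each compatible: a component omitted on either
#' side is a wildcard, a policy flag can ignore it altogether, and otherwise
#' it must agree. So the shortened query `miR-301b` matches the full reference
#' `hsa-miR-301b-3p` under any policy.
#'
#' @param query,reference Parsed identifier tibbles (from
#'   [parse_mirna_ids()]), recycled against each other row-wise when one has
#'   a single row.
#' @param policy A [match_policy()].
#'
#' @return Logical vector.
#' @examples
#' q <- parse_mirna_ids("miR-301b")
#' r <- parse_mirna_ids("hsa-miR-301b-3p")
#' mirna_match(q, r)
#' @export
mirna_match <- function(query, reference, policy = match_policy()) {
  stopifnot(inherits(policy, "match_policy"))
  n <- max(nrow(query), nrow(reference))
  rec <- function(v) if (length(v) == 1L) rep(v, n) else v
  qp <- rec(query$species_prefix); rp <- rec(reference$species_prefix)
  qc <- rec(query$core);           rc <- rec(reference$core)
  qa <- rec(query$arm);            ra <- rec(reference$arm)

  if (policy$case_insensitive_core) {
    qc <- tolower(qc); rc <- tolower(rc)
  }
  core_ok <- qc == rc
  prefix_ok <- policy$ignore_species_prefix | is.na(qp) | is.na(rp) | qp == rp
  arm_ok <- policy$cluster_arms | is.na(qa) | is.na(ra) | qa == ra
  core_ok & prefix_ok & arm_ok
}

#' Read a miRNA identifier list
#'
#' One identifier per line; lines starting with `#` are ignored and
#' surrounding whitespace is trimmed. Parsing failures are reported, not
#' fatal (see [parse_mirna_ids()]).
#'
#' @param path Path to a plain-text file.
#' @return A parsed identifier tibble; `attr(, "n_raw")` holds the number of
#'   non-comment input lines and `attr(, "skipped")` the rejected ones.
#' @export
read_mirna_list <- function(path) {
  lines <- readr::read_lines(path)
  lines <- stringr::str_trim(lines)
  lines <- lines[lines != "" & !stringr::str_starts(lines, "#")]
  out <- parse_mirna_ids(lines)
  attr(out, "n_raw") <- length(lines)
  out
}
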