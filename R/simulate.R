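# Synthetic-data generators: every module is testable without downloads.
# All generators are pure functions of their arguments — the seed fully
# determines the output and the caller's RNG state is left untouched.

# deterministic pseudo-Latin binomial labels, e.g. "Dalora_vetis"
make_binomials <- function(n) {
  syll <- c("ba", "ce", "da", "fe", "gi", "ho", "ka", "lo", "mi", "nu",
            "pa", "re", "sa", "ti", "vu", "xa", "ze", "or", "ul", "an")
  words <- function(m, k) {
    draws <- matrix(syll[sample.int(length(syll), m * k, replace = TRUE)], nrow = m)
    apply(draws, 1, paste, collapse = "")
  }
  out <- character(0)
  while (length(out) < n) {
    m <- max(64L, 2L * (n - length(out)))
    g <- words(m, 3)
    genus <- paste0(toupper(substr(g, 1, 1)), substr(g, 2, 6))
    cand <- paste0(genus, "_", words(m, 3), "is")
    out <- unique(c(out, cand))
  }
  out[seq_len(n)]
}

#' Generate a random rooted tree
#'
#' Equal-rates (Yule-like) random branching via [ape::rtree()], with unique
#' binomial-style tip labels, optional polytomies, and optional uniform
#' branch lengths.  Output is fully determined by the arguments; the global
#' RNG state is not disturbed.
#'
#' @param n_tips number of tips (>= 1).
#' @param seed integer seed; same seed, same tree.
#' @param lengths attach branch lengths (uniform on (0, 1])? Default `TRUE`.
#' @param polytomy_prob probability that an internal edge is collapsed into
#'   a polytomy (default 0 = binary tree).
#' @param label_pool optional character vector to draw tip labels from.
#' @return a `phylo`.
#' @export
random_tree <- function(n_tips, seed, lengths = TRUE, polytomy_prob = 0,
                        label_pool = NULL) {
  stopifnot(n_tips >= 1)
  withr::with_seed(seed, {
    labels <- if (is.null(label_pool)) make_binomials(n_tips)
              else sample(label_pool, n_tips)
    if (n_tips == 1) {
      return(build_phylo(ids = 1L, parent = 0L, label = labels,
                         length = if (lengths) stats::runif(1) else NA_real_,
                         is_tip = TRUE, ord = 1))
    }
    tr <- ape::rtree(n_tips, rooted = TRUE)
    tr$tip.label <- labels
    tr$edge.length <- stats::runif(nrow(tr$edge))
    if (polytomy_prob > 0 && tr$Nnode > 1) {
      internal <- which(tr$edge[, 2] > ape::Ntip(tr))
      collapse <- internal[stats::runif(length(internal)) < polytomy_prob]
      if (length(collapse)) {
        keep_len <- tr$edge.length
        tr$edge.length[collapse] <- 0
        tr <- ape::di2multi(tr, tol = 1e-12)
        if (!lengths) tr$edge.length <- NULL
        tr <- normalize_phylo(tr)
        validate_tree(tr)
        return(tr)
      }
    }
    if (!lengths) tr$edge.length <- NULL
    validate_tree(tr)
    tr
  })
}

#' Generate a random ultrametric tree (chronogram)
#'
#' Coalescent branching via [ape::rcoal()], rescaled so every root-to-tip
#' path length equals `age_root` exactly.
#'
#' @inheritParams random_tree
#' @param age_root root age (time units; tips sit at age 0). Default 10.
#' @return an ultrametric `phylo`.
#' @export
random_ultrametric_tree <- function(n_tips, seed, age_root = 10,
                                    label_pool = NULL) {
  stopifnot(n_tips >= 1, age_root > 0)
  withr::with_seed(seed, {
    labels <- if (is.null(label_pool)) make_binomials(n_tips)
              else sample(label_pool, n_tips)
    if (n_tips == 1) {
      return(build_phylo(ids = 1L, parent = 0L, label = labels,
                         length = age_root, is_tip = TRUE, ord = 1))
    }
    tr <- ape::rcoal(n_tips)
    tr$tip.label <- labels
    depth <- max(node_depths(tr)[seq_len(n_tips)])
    tr$edge.length <- tr$edge.length * (age_root / depth)
    # kill rescaling round-off: stretch each tip edge to land exactly on 0
    d <- node_depths(tr)
    tipe <- match(seq_len(n_tips), tr$edge[, 2])
    tr$edge.length[tipe] <- tr$edge.length[tipe] + (age_root - d[seq_len(n_tips)])
    validate_tree(tr)
    tr
  })
}

#' Generate an MSW3-like taxonomy table
#'
#' Rows of genus/species (optionally taken from a companion tree's tip
#' labels), a higher-rank Family column grouping genera, an Author column,
#' and a free-text Synonyms column embedding italic-tagged alternate names
#' for a stated fraction of rows — the layout the CSV-backed resolver
#' adaptors expect.
#'
#' @param n number of rows (ignored when `tips` is given).
#' @param seed integer seed.
#' @param synonym_fraction fraction of rows given an italic-tagged synonym
#'   (default 0.3).
#' @param tips optional character vector of `Genus_species` tip labels the
#'   table must cover.
#' @param source_id source identifier (default `"synth"`).
#' @return a `taxonomy_table`; every embedded synonym is recoverable by
#'   [match_msw3()] technique 2.
#' @export
random_taxonomy <- function(n, seed, synonym_fraction = 0.3, tips = NULL,
                            source_id = "synth") {
  withr::with_seed(seed, {
    binom <- if (is.null(tips)) make_binomials(n) else tips
    n <- length(binom)
    parts <- strsplit(gsub("_", " ", binom), " ")
    genus <- vapply(parts, `[`, character(1), 1)
    species <- vapply(parts, function(p) paste(p[-1], collapse = " "), character(1))
    fams <- paste0(unique(genus), "idae")
    family <- fams[match(genus, unique(genus))]
    author <- sprintf("Author, %d", sample(1750:1990, n, replace = TRUE))
    syn_pool <- make_binomials(n + 5L)
    syn_pool <- setdiff(syn_pool, binom)
    synonyms <- rep("", n)
    take <- which(stats::runif(n) < synonym_fraction)
    take <- take[seq_len(min(length(take), length(syn_pool)))]
    for (k in seq_along(take)) {
      synonyms[take[k]] <- sprintf("<i>%s</i> %s.",
                                   gsub("_", " ", syn_pool[k]),
                                   sample(c("Gray", "Kerr", "Linnaeus"), 1))
    }
    as_taxonomy(data.frame(Genus = genus, Species = species, Family = family,
                           Author = author, Synonyms = synonyms,
                           stringsAsFactors = FALSE),
                source_id = source_id)
  })
}

#' Corrupt a name by a fixed number of single-character edits
#'
#' Applies exactly `n_edits` random character substitutions, insertions or
#' deletions, re-drawing until the Levenshtein distance to the original is
#' exactly `n_edits` (edits can otherwise cancel).  Deterministic per seed.
#'
#' @param name the name to corrupt.
#' @param n_edits number of edits (0 returns the name unchanged).
#' @param seed integer seed.
#' @return the corrupted name.
#' @export
corrupt_name <- function(name, n_edits = 1, seed = 1) {
  if (n_edits == 0) return(name)
  alphabet <- c(letters, " ")
  withr::with_seed(seed, {
    for (attempt in 1:50) {
      out <- name
      for (e in seq_len(n_edits)) {
        chars <- strsplit(out, "")[[1]]
        op <- sample(c("sub", "ins", "del"), 1)
        i <- sample.int(length(chars), 1)
        if (op == "sub") chars[i] <- sample(setdiff(alphabet, tolower(chars[i])), 1)
        else if (op == "ins") chars <- append(chars, sample(alphabet, 1), after = i)
        else if (length(chars) > 1) chars <- chars[-i]
        out <- paste(chars, collapse = "")
      }
      if (as.integer(utils::adist(out, name)) == n_edits) return(out)
    }
    stop("could not corrupt \"", name, "\" to exactly ", n_edits, " edits")
  })
}

#' The packaged mammal example
#'
#' A 20-tip mammal tree (no branch lengths, no internal labels — the shape
#' of a taxonomy-derived megatree) in which Homo_sapiens and Pan_troglodytes
#' are sister tips and Mus_musculus sits outside that clade, plus a matching
#' MSW3-style taxonomy table covering every tip (with a few italic-tagged
#' synonyms and all higher ranks filled in).  Pruning the tree to
#' Homo_sapiens, Pan_troglodytes and Mus_musculus yields exactly
#' `"((Homo_sapiens,Pan_troglodytes),Mus_musculus);"`.
#'
#' @return a list with components `tree` (`phylo`) and `taxonomy`
#'   (`taxonomy_table`).
#' @examples
#' fx <- mammal_fixture()
#' pr <- prune_tree(fx$tree, c("Homo_sapiens", "Pan_troglodytes", "Mus_musculus"))
#' write_newick(pr$tree)
#' @export
mammal_fixture <- function() {
  nwk <- paste0(
    "((((((Homo_sapiens,Pan_troglodytes),Gorilla_gorilla),Pongo_pygmaeus),",
    "(Macaca_mulatta,Papio_anubis)),",
    "(((Mus_musculus,Rattus_norvegicus),(Cavia_porcellus,Sciurus_vulgaris)),",
    "Oryctolagus_cuniculus)),",
    "((Canis_lupus,Felis_catus),(Bos_taurus,Sus_scrofa),Equus_caballus),",
    "Loxodonta_africana,Dasypus_novemcinctus,Monodelphis_domestica,",
    "Ornithorhynchus_anatinus);")
  tree <- read_newick(text = nwk)
  tax <- data.frame(
    Order = c("Primates", "Primates", "Primates", "Primates", "Primates",
              "Primates", "Rodentia", "Rodentia", "Rodentia", "Rodentia",
              "Lagomorpha", "Carnivora", "Carnivora", "Artiodactyla",
              "Artiodactyla", "Perissodactyla", "Proboscidea", "Cingulata",
              "Didelphimorphia", "Monotremata"),
    Family = c("Hominidae", "Hominidae", "Hominidae", "Hominidae",
               "Cercopithecidae", "Cercopithecidae", "Muridae", "Muridae",
               "Caviidae", "Sciuridae", "Leporidae", "Canidae", "Felidae",
               "Bovidae", "Suidae", "Equidae", "Elephantidae",
               "Dasypodidae", "Didelphidae", "Ornithorhynchidae"),
    Genus = c("Homo", "Pan", "Gorilla", "Pongo", "Macaca", "Papio", "Mus",
              "Rattus", "Cavia", "Sciurus", "Oryctolagus", "Canis", "Felis",
              "Bos", "Sus", "Equus", "Loxodonta", "Dasypus", "Monodelphis",
              "Ornithorhynchus"),
    Species = c("sapiens", "troglodytes", "gorilla", "pygmaeus", "mulatta",
                "anubis", "musculus", "norvegicus", "porcellus", "vulgaris",
                "cuniculus", "lupus", "catus", "taurus", "scrofa",
                "caballus", "africana", "novemcinctus", "domestica",
                "anatinus"),
    Author = c("Linnaeus, 1758", "Blumenbach, 1775", "Savage, 1847",
               "Lacepede, 1799", "Zimmermann, 1780", "Lesson, 1827",
               "Linnaeus, 1758", "Berkenhout, 1769", "Linnaeus, 1758",
               "Linnaeus, 1758", "Linnaeus, 1758", "Linnaeus, 1758",
               "Linnaeus, 1758", "Linnaeus, 1758", "Linnaeus, 1758",
               "Linnaeus, 1758", "Blumenbach, 1797", "Linnaeus, 1758",
               "Wagner, 1842", "Shaw, 1799"),
    Synonyms = c("", "<i>Simia troglodytes</i> Blumenbach.",
                 "<i>Troglodytes gorilla</i> Savage.", "",
                 "<i>Simia mulatta</i> Zimmermann.", "", "",
                 "<i>Mus norvegicus</i> Berkenhout.", "", "", "",
                 "<i>Canis familiaris</i> Linnaeus.",
                 "<i>Felis silvestris catus</i>.", "", "", "",
                 "<i>Elephas africanus</i> Blumenbach.", "", "", ""),
    stringsAsFactors = FALSE
  )
  list(tree = tree, taxonomy = as_taxonomy(tax, "msw3-fixture"))
}
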