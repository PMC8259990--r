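# Label inventories for the three auxiliary prediction tracks.

#' Universal part-of-speech tag inventory
#'
#' The coarse POS tags emitted by spaCy-family annotators, plus `SPACE`,
#' which doubles as the null tag for subwords outside any annotated word
#' span (whitespace, special tokens).
#' @export
POS_TAGS <- c("ADJ", "ADP", "ADV", "AUX", "CCONJ", "DET", "INTJ", "NOUN",
              "NUM", "PART", "PRON", "PROPN", "PUNCT", "SCONJ", "SYM",
              "VERB", "X", "SPACE")

#' Dependency-relation tag inventory
#'
#' A compact set of common dependency labels; `dep` (the unspecified
#' relation) doubles as the null tag for unannotated subwords.
#' @export
DEP_TAGS <- c("ROOT", "acl", "advcl", "advmod", "amod", "appos", "attr",
              "aux", "auxpass", "case", "cc", "ccomp", "compound", "conj",
              "det", "dobj", "mark", "neg", "nmod", "npadvmod", "nsubj",
              "nsubjpass", "nummod", "pobj", "poss", "prep", "punct",
              "relcl", "xcomp", "dep")

#' Entity-class inventory
#'
#' The 14 entity classes produced by annotators trained on the BioNLP13CG
#' corpus (cancer genetics), plus the explicit "not an entity" class, for a
#' 15-way entity track.
#' @export
ENTITY_CLASSES <- c("cancer", "organ", "tissue", "organism", "cell",
                    "amino_acid", "gene_or_gene_product", "simple_chemical",
                    "anatomical_system", "immaterial_anatomical_entity",
                    "multi_tissue_structure",
                    "developing_anatomical_structure",
                    "organism_subdivision", "cellular_component",
                    "not_an_entity")

NULL_POS <- "SPACE"
NULL_DEP <- "dep"
NULL_ENT <- "not_an_entity"

label_to_id <- function(labels, inventory, track) {
  ids <- match(labels, inventory)
  if (anyNA(ids))
    stopf("unknown %s label(s): %s", track,
          paste(unique(labels[is.na(ids)]), collapse = ", "))
  ids
}
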