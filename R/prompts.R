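# System prompt templates.
#
# The inline prompt asks for five "___"-separated values per sample; the
# "better" variant adds one clarifying clause for the two label conventions
# that trip up both models and humans (rhizosphere -> plant, sediment ->
# water); the json variant requests structured output instead of inline
# formatting. The json template's exact schema wording is a reconstruction
# and is documented as such.

better_prompt_clause <- function() {
  "Please note that rhizosphere samples should be categorized as 'plant' and sediment samples as 'water'."
}

standard_prompt_text <- function() {
  paste(
    "We kindly request your expertise in analyzing the following microbial metagenomic samples from their metadata texts:",
    "",
    paste0("1. Please deduce the source category for the sample, choosing from ",
           "\"animal\" (including humans), \"plant\", \"water\", \"soil\", or \"other\". ",
           "Your choices are \"animal\" (incl. human), \"plant\", \"water\", \"soil\", and \"other\". ",
           "Give strictly a concise, single-word label for the sample ID."),
    "2. Please infer geographical location where the sample was collected, including the country (NOT the coordinates).",
    "3. Extract strictly 5–8 keywords descriptive of the sample origin, separated by commas. Put them within curly brackets.",
    paste0("4. We seek a brief, up to 3-word description of the sample's specific origin. ",
           "For \"animal\" or \"plant\" sources, please specify the host and part thereof. ",
           "For \"water\" samples, the type of water body is sought (e.g., lake, brine, sea, wastewater, etc.). ",
           "If from \"soil\", specify (e.g., agricultural, desert, forest, etc.). ",
           "If from \"other\" specify which (e.g., urban, laboratory, feed/food, fungus, air, etc.)."),
    "",
    "If information is missing, kindly indicate \"NA\". Please separate all values with 3 underscores (\"___\").",
    "",
    paste0("An example response: SRS123456___animal___Los Angeles, USA___",
           "{medical, bone fracture, infection, collagen, hospital, intensive care, cast, ",
           "Staphylococcus epidermidis}___human elbow"),
    sep = "\n"
  )
}

json_prompt_text <- function() {
  paste(
    "We kindly request your expertise in analyzing the following microbial metagenomic samples from their metadata texts:",
    "",
    paste0("1. Please deduce the source category for the sample, choosing from ",
           "\"animal\" (including humans), \"plant\", \"water\", \"soil\", or \"other\". ",
           "Your choices are \"animal\" (incl. human), \"plant\", \"water\", \"soil\", and \"other\". ",
           "Give strictly a concise, single-word label for the sample ID."),
    "2. Please infer geographical location where the sample was collected, including the country (NOT the coordinates).",
    "3. Extract strictly 5–8 keywords descriptive of the sample origin.",
    paste0("4. We seek a brief, up to 3-word description of the sample's specific origin. ",
           "For \"animal\" or \"plant\" sources, please specify the host and part thereof. ",
           "For \"water\" samples, the type of water body is sought (e.g., lake, brine, sea, wastewater, etc.). ",
           "If from \"soil\", specify (e.g., agricultural, desert, forest, etc.). ",
           "If from \"other\" specify which (e.g., urban, laboratory, feed/food, fungus, air, etc.)."),
    "",
    paste0("If information is missing, kindly indicate \"NA\". ",
           "Please generate the output in a JSON format: a JSON array with one object per sample, ",
           "each with keys \"sample_id\", \"biome\", \"location\", \"keywords\" ",
           "(an array of 5–8 strings), and \"sub_biome\"."),
    sep = "\n"
  )
}

#' Build a system prompt
#'
#' Three variants are supported. `standard_inline` asks for five
#' triple-underscore-separated values per sample (biome, location, 5-8
#' keywords in curly brackets, up to 3-word sub-biome). `better_inline`
#' appends a single clarifying clause instructing that rhizosphere samples
#' be labelled plant and sediment samples water. `json` requests the same
#' content as a JSON array.
#'
#' @param variant One of `"standard_inline"`, `"better_inline"`, `"json"`.
#' @return The full system prompt string (byte-identical across calls).
#' @export
build_system_prompt <- function(variant = c("standard_inline", "better_inline", "json")) {
  variant <- match.arg(variant)
  switch(variant,
    standard_inline = standard_prompt_text(),
    better_inline = paste0(standard_prompt_text(), "\n\n", better_prompt_clause()),
    json = json_prompt_text()
  )
}
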