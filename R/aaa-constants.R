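# Shared token sets. P1 is the maternal parental line (SD-type), P2 the
# paternal line (SC-type); calls are serialized as AA / AB / BB / NA.
.geno_tokens <- c("AA", "AB", "BB")
.cohorts <- c("f2_nauplii", "f2_adult_male", "nrbc_adult_male")
.sexes <- c("male", "female", "unknown")
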