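# Template catalog of known A-to-I editing sites for an alpha6-type nAChR
# transcript.  Site labels follow the external numbering used in the alpha6
# editing literature; transcript_pos values are placeholders and MUST be
# set by the user for the transcript build under study (the numbering
# depends on the transcript isoform and annotation release).
# classify_known_sites() labels each row candidate_edit /
# genomically_encoded / not_detected.
gene	site_label	transcript_pos	edited_base
alpha6	site1	0	G
alpha6	site2	0	G
alpha6	site3	0	G
alpha6	site4	0	G
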