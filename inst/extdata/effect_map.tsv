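# Mapping from annotation-tool effect labels (ANNOVAR-style) to the
# controlled effect vocabulary used throughout the package.
source_label	effect
stopgain	stopgain
stopgain SNV	stopgain
frameshift insertion	frameshift_insertion
frameshift deletion	frameshift_deletion
frameshift substitution	other
nonframeshift insertion	nonframeshift_insertion
nonframeshift deletion	nonframeshift_deletion
splicing donor	splice_donor
splicing acceptor	splice_acceptor
splice donor	splice_donor
splice acceptor	splice_acceptor
nonsynonymous SNV	missense
missense SNV	missense
synonymous SNV	synonymous
stoploss	other
stoploss SNV	other
unknown	other
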