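# Viral hallmark product terms (case-insensitive substring match).
# Seeded from annotated core proteins of T7-like cyanopodoviruses:
# capsid/tail/portal structural genes and replication-module genes that
# are common across tailed phages but absent from cellular genomes.
capsid
terminase
portal
tail
DNA polymerase
primase
helicase
scaffold
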