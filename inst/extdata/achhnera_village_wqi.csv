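village,wqi
Arsena,158.115
Biara,164.838
Janutha,140.294
Kukathala,122.349
Loh Karera,162.857
Raibha,185.866
Mahuar,99.323
Runkata,152.101
Sehta,124.867
Achhnera,131.918
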