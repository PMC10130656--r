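# Budding yeast cytoplasmic ribosomal protein genes:
# 40S (RPS), 60S (RPL) and 60S-acidic (RPP) families, paralogs included.
RPS2
RPS3
RPS5
RPS12
RPS13
RPS15
RPS20
RPS31
RPS0A
RPS0B
RPS1A
RPS1B
RPS4A
RPS4B
RPS6A
RPS6B
RPS7A
RPS7B
RPS8A
RPS8B
RPS9A
RPS9B
RPS10A
RPS10B
RPS11A
RPS11B
RPS14A
RPS14B
RPS16A
RPS16B
RPS17A
RPS17B
RPS18A
RPS18B
RPS19A
RPS19B
RPS21A
RPS21B
RPS22A
RPS22B
RPS23A
RPS23B
RPS24A
RPS24B
RPS25A
RPS25B
RPS26A
RPS26B
RPS27A
RPS27B
RPS28A
RPS28B
RPS29A
RPS29B
RPS30A
RPS30B
RPL3
RPL5
RPL10
RPL25
RPL28
RPL29
RPL30
RPL32
RPL38
RPL39
RPL1A
RPL1B
RPL2A
RPL2B
RPL4A
RPL4B
RPL6A
RPL6B
RPL7A
RPL7B
RPL8A
RPL8B
RPL9A
RPL9B
RPL11A
RPL11B
RPL12A
RPL12B
RPL13A
RPL13B
RPL14A
RPL14B
RPL15A
RPL15B
RPL16A
RPL16B
RPL17A
RPL17B
RPL18A
RPL18B
RPL19A
RPL19B
RPL20A
RPL20B
RPL21A
RPL21B
RPL22A
RPL22B
RPL23A
RPL23B
RPL24A
RPL24B
RPL26A
RPL26B
RPL27A
RPL27B
RPL31A
RPL31B
RPL33A
RPL33B
RPL34A
RPL34B
RPL35A
RPL35B
RPL36A
RPL36B
RPL37A
RPL37B
RPL40A
RPL40B
RPL41A
RPL41B
RPL42A
RPL42B
RPL43A
RPL43B
RPP0
RPP1A
RPP1B
RPP2A
RPP2B
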