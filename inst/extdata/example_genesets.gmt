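development_program	synthetic example term	HG00001	HG00002	HG00003	HG00004	HG00005	HG00006
inflammatory_response	synthetic example term	HG00010	HG00011	HG00012	HG00013
housekeeping	synthetic example term	HG00020	HG00021	HG00022	HG00023	HG00024	HG00025	HG00026	HG00027
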