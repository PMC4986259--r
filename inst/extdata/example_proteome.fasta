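>syn|P00000
LPCRDANSCSWGSMLNRVQDDWMCKANDFNEHNMSDCGPQADCANPWAWAYKPKANVKYI
QDMCTYSWHNIQPSQCRGRYRFIAYWDGKMWHFWQVWGLRTSENQCDEIAVLYSADYYPG
RVSTHYCPRYTYYAMQNQLSSVD
>syn|P00001
RNKGRQPQGKFCIDDQTYNWHGGAVHANMDPEYWDYGCKKMHYNLYDFARHQGDYLYHWS
WRAGHVHSKCCVASTGLDDITFREEYHWDFPEVFYAPTDVTPSYASPG
>syn|P00002
YSGCACQEQPERYIAITEEWHNSQKKMGELYIFYKVHFHSDYKMTIHNKECWDYEETWKE
RRAACIQFDWKEVMIMKHCCRPESYSNEMWQLMKSMPKIGCYWWVWMELKSPRFFPFSFP
HQYAQKWRVPIRCINPFFCVFGACQRVAVMQTPFFV
>syn|P00003
WLCAKPLFWTSLWRHGDCKGTRLCFQRHDAIDSKVCTGWQEEYDVNQGTATCKPTMKDLV
FKAPHSWTEIGWTKRWQFKSDNEYKLDVRIIRC
>syn|P00004
HVTSWTKPKPLTQWKMTMRMEHNACPEWCWGPPSTMMGLNYNWGGWASSCCGTVEMKNRA
QSWQHPENEEEVRAGENQVPLLDTEYKFHHELMENDCGVVATERKFIWEGC
>syn|P00005
DGWTEHHLKYPRDQICIVLMVEASPNRIEKAAFRQDGCIMNFDHLLRGRVHCCHSWWLGC
HQELFVVFPFSDSVAQLRKAWWRADDLHIEYSQAEMSKSQHQECKGIWYPICDASDGSPT
GVPRPFHCHMY
>syn|P00006
NYDGQASRPWHEEFNEQRDSSYVCVLCKSWCSWKWYNIFRIAVSCGQEYHKKKYPSIRNT
PN
>syn|P00007
PPQSMCCDCTNHEHYCSQDESLTVDKHFVWQYYIGTTNWWSNIKHPHQCKIQKLQLWHIQ
WDTIGHMQVVDPHKPGMKLKTIFPWHGEQLCKRWRDSVTPWFT
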