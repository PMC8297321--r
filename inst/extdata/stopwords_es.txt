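# Base Spanish stopword list, diacritics pre-folded (see normalize_term).
# One term per line. Function words, auxiliaries, frequent adverbs and a few
# social-media artifacts.
el
la
los
las
lo
un
una
uno
unos
unas
al
del
a
ante
bajo
con
contra
de
desde
durante
en
entre
hacia
hasta
mediante
para
por
segun
sin
sobre
tras
y
e
ni
o
u
que
como
cuando
donde
mientras
aunque
porque
pues
si
pero
sino
mas
menos
yo
tu
el
ella
ello
nosotros
nosotras
vosotros
vosotras
ellos
ellas
usted
ustedes
me
te
se
nos
os
le
les
mi
mis
tus
su
sus
nuestro
nuestra
nuestros
nuestras
vuestro
vuestra
vuestros
vuestras
este
esta
estos
estas
esto
ese
esa
esos
esas
eso
aquel
aquella
aquellos
aquellas
aquello
ser
es
soy
eres
somos
sois
son
era
eras
eramos
erais
eran
fui
fuiste
fue
fuimos
fuisteis
fueron
sere
sera
seran
siendo
sido
estar
estoy
estamos
estais
estan
estaba
estabas
estabamos
estaban
estuve
estuvo
estuvieron
estare
estara
estaran
estando
estado
haber
he
has
ha
hemos
habeis
han
habia
habias
habiamos
habian
hube
hubo
habra
habran
habiendo
habido
hay
tener
tengo
tienes
tiene
tenemos
teneis
tienen
tenia
tenian
tuvo
tuvieron
tendra
hacer
hago
haces
hace
hacemos
hacen
hacian
hizo
hicieron
hara
ir
voy
vas
va
vamos
vais
van
iba
iban
poder
puedo
puedes
puede
podemos
pueden
podia
pudo
podra
decir
digo
dices
dice
dicen
dijo
dijeron
dira
no
ya
muy
mucho
muchos
mucha
muchas
poco
pocos
poca
pocas
tan
tanto
tanta
tantos
tantas
tal
tales
algo
alguien
alguno
alguna
algunos
algunas
nada
nadie
ninguno
ninguna
todo
toda
todos
todas
otro
otra
otros
otras
mismo
misma
mismos
mismas
cada
cual
cuales
quien
quienes
cuyo
cuya
cuanto
cuanta
cuantos
cuantas
aqui
alli
ahi
alla
aca
ahora
antes
despues
luego
pronto
tarde
hoy
ayer
manana
siempre
nunca
jamas
tambien
tampoco
solo
solamente
bien
mal
mejor
peor
bastante
demasiado
casi
apenas
entonces
asi
aun
incluso
ademas
embargo
obstante
vez
veces
rt
jaja
jajaja
xq
pq
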